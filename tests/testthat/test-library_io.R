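test_that("apply_mutations substitutes, preserves length, and validates", {
  base <- toy_base("ACDEF")
  expect_equal(apply_mutations(base, "D3Y"), "ACYEF")
  expect_equal(apply_mutations(base, ""), "ACDEF")
  expect_equal(apply_mutations(base, "A1C;F5W"), "CCDEW")
  # ref mismatch names the position
  expect_error(apply_mutations(base, "E3Y"), "position 3")
  expect_error(apply_mutations(base, "A9C"), "out of range")
  # numbering offset shifts positions
  base10 <- base_construct("ACDEF", offset = 10L)
  expect_equal(apply_mutations(base10, "D12Y"), "ACYEF")
  expect_error(apply_mutations(base10, "D3Y"), "out of range")
})

test_that("mutation parsing rejects malformed tokens", {
  expect_equal(nrow(parse_mutation_string("L317H;Q305D")), 2)
  expect_error(parse_mutation_string("L317"), "unparseable")
  expect_error(parse_mutation_string("317H"), "unparseable")
  expect_error(parse_mutation_string("B317H"), "non-canonical")
})

test_that("apply_mutations / diff_sequences round-trip recovers mutations", {
  set.seed(11)
  base <- base_construct(synthetic_base_sequence(40, seed = 3))
  chars <- strsplit(base$sequence, "", fixed = TRUE)[[1]]
  for (i in 1:20) {
    pos <- sort(sample(40, sample(1:4, 1)))
    alt <- vapply(pos, function(p) sample(setdiff(c("A", "C", "D", "E", "F",
      "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W",
      "Y"), chars[p]), 1), "")
    mut <- data.frame(pos = pos, ref = chars[pos], alt = alt)
    seq <- apply_mutations(base, mut)
    expect_equal(diff_sequences(base, seq), mut, ignore_attr = TRUE)
  }
})

test_that("parse_variant_table yields an L + 2 column table and lifts sequences", {
  lib <- toy_library()
  tab <- sequence_table(lib)
  expect_equal(ncol(tab), 5 + 2)
  expect_equal(tab$id, c("v1", "v2", "v3"))
  # v2 = A1C;F5W differs from base at positions 1 and 5
  d <- diff_sequences(lib$base, lib$variants$sequence[2])
  expect_equal(d$pos, c(1L, 5L))
  # rows missing the target are dropped with a warning
  rows <- data.frame(id = c("a", "b"), mutations = c("D3Y", ""),
                     dff = c(1, NA))
  expect_warning(lib2 <- parse_variant_table(rows, toy_base(), "dff"),
                 "dropping 1")
  expect_equal(n_variants(lib2), 1)
  # unparseable mutation token names the row
  rows_bad <- data.frame(id = "x", mutations = "D3", dff = 1)
  expect_error(parse_variant_table(rows_bad, toy_base(), "dff"), "'x'")
  # source namespacing prevents id collisions across datasets
  libA <- parse_variant_table(data.frame(id = "v", mutations = "D3Y", dff = 1),
                              toy_base(), "dff", source = "chen")
  expect_equal(libA$variants$id, "chen:v")
})

test_that("deduplicate_average means duplicates and keeps smallest id", {
  rows <- data.frame(id = c("z9", "a1", "m5", "solo"),
                     mutations = c("D3Y", "D3Y", "D3Y", "A1C"),
                     dff = c(0.8, 1.2, 6.1, 2.0))
  lib <- deduplicate_average(parse_variant_table(rows, toy_base(), "dff"))
  expect_equal(n_variants(lib), 2)
  dup <- lib$variants[lib$variants$mutations == "D3Y", ]
  expect_equal(dup$id, "a1")
  expect_equal(dup$dff, mean(c(0.8, 1.2, 6.1)))
  # arithmetic-mean oracle {1,2,6} -> 3
  rows2 <- data.frame(id = c("a", "b", "c"), mutations = "D3Y",
                      dff = c(1, 2, 6))
  expect_equal(deduplicate_average(
    parse_variant_table(rows2, toy_base(), "dff"))$variants$dff, 3)
  # idempotent, and identity on duplicate-free input
  expect_identical(deduplicate_average(lib), lib)
})

test_that("normalize_to_reference divides through and preserves ratios", {
  rows <- data.frame(id = c("r", "v"), mutations = c("", "D3Y"),
                     dff = c(2.0, 3.0))
  lib <- parse_variant_table(rows, toy_base(), "dff")
  nl <- normalize_to_reference(lib, "r")
  expect_equal(target_values(nl), c(r = 1.0, v = 1.5))
  # ratio invariance
  expect_equal(target_values(nl)[["v"]] / target_values(nl)[["r"]],
               target_values(lib)[["v"]] / target_values(lib)[["r"]])
  expect_error(normalize_to_reference(lib, "nope"), "not found")
  rows$dff[1] <- 0
  lib0 <- parse_variant_table(rows, toy_base(), "dff")
  expect_error(normalize_to_reference(lib0, "r"), "zero")
})

test_that("split_train_test floors the train size and is a seeded partition", {
  setup <- small_sweep_setup(n_variants = 50)
  lib <- setup$lib
  n <- n_variants(lib)
  sp <- split_train_test(lib, 0.8, 42)
  expect_equal(length(sp$train_ids), floor(0.8 * n))
  expect_setequal(c(sp$train_ids, sp$test_ids), lib$variants$id)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # determinism
  sp2 <- split_train_test(lib, 0.8, 42)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train_ids,
                         split_train_test(lib, 0.8, 43)$train_ids))
  # the canonical 1078-record split: floor(0.8 * 1078) = 862 train / 216 test
  base60 <- base_construct(synthetic_base_sequence(60, seed = 9))
  chars <- strsplit(base60$sequence, "", fixed = TRUE)[[1]]
  grid <- expand.grid(pos = 1:60, alt = c("A", "C", "D", "E", "F", "G", "H",
    "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    stringsAsFactors = FALSE)
  grid <- grid[chars[grid$pos] != grid$alt, ][1:1078, ]
  rows <- data.frame(
    id = sprintf("m%04d", seq_len(1078)),
    mutations = paste0(chars[grid$pos], grid$pos, grid$alt),
    dff = 1)
  big <- parse_variant_table(rows, base60, "dff")
  sp3 <- split_train_test(big, 0.8, 42)
  expect_equal(length(sp3$train_ids), 862)
  expect_equal(length(sp3$test_ids), 216)
})

test_that("library CSV and split JSON round-trip", {
  lib <- toy_library()
  csv <- tempfile(fileext = ".csv")
  write_variant_csv(lib, csv)
  lib2 <- read_variant_csv(csv, lib$base, "dff")
  expect_equal(lib2$variants, lib$variants)

  sp <- split_train_test(small_sweep_setup(n_variants = 40)$lib, 0.75, 7)
  js <- tempfile(fileext = ".json")
  write_split_json(sp, js)
  expect_equal(read_split_json(js), sp)
})

test_that("FASTA round-trip preserves the base construct", {
  base <- base_construct(synthetic_base_sequence(130, seed = 2), name = "bc1")
  fa <- tempfile(fileext = ".fasta")
  write_base_fasta(base, fa)
  back <- read_base_fasta(fa)
  expect_equal(back$sequence, base$sequence)
  expect_equal(back$name, "bc1")
})
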