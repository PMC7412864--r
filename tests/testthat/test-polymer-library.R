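test_that("polymer id formatting and parsing are inverse", {
  ids <- format_polymer_id(c("A", "B", "C"), c(5, 12, 1),
                           c("e2", "none", "e1"))
  expect_equal(ids, c("A5-e2", "B12", "C1-e1"))
  parsed <- parse_polymer_id(ids)
  expect_equal(parsed$acrylate, c("A", "B", "C"))
  expect_equal(parsed$amine, c(5L, 12L, 1L))
  expect_equal(parsed$endcap, c("e2", "none", "e1"))
  expect_error(parse_polymer_id("5A"), "malformed")
  expect_error(format_polymer_id("A", 5, "e9"), "endcap")
})

test_that("descriptor table constructor enforces invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  tab <- descriptor_table(m, polymer_ids = c("A1", "A2"))
  expect_equal(dim(tab), c(2L, 3L))
  expect_error(descriptor_table(m, polymer_ids = c("A5", "A5")), "A5")
  m2 <- m; colnames(m2) <- c("a", "a", "c")
  expect_error(descriptor_table(m2, polymer_ids = c("A1", "A2")),
               "duplicate descriptor")
  m3 <- m; m3[1, 2] <- NA
  expect_error(descriptor_table(m3, polymer_ids = c("A1", "A2")),
               "non-finite")
})

test_that("CSV round trip is the identity on values and ids", {
  lib <- generate_library(library_sim_config(n_amines = 6, n_acrylates = 2,
                                             n_descriptors = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(lib$descriptors, path)
  reread <- suppressMessages(read_descriptor_table(path))
  expect_equal(reread$polymer_ids, lib$descriptors$polymer_ids)
  expect_equal(reread$values, lib$descriptors$values, tolerance = 1e-12)
})

test_that("CSV loader reports dimensions and rejects bad cells", {
  df <- data.frame(polymer_id = c("A1", "A2", "A2"), d1 = 1:3, d2 = 4:6)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(suppressMessages(read_descriptor_table(path)), "A2")
  df2 <- data.frame(polymer_id = c("A1", "A2"), d1 = c(1, NA), d2 = c(4, 6))
  write.csv(df2, path, row.names = FALSE)
  expect_error(suppressMessages(read_descriptor_table(path)),
               "row 2.*d1")
  df3 <- data.frame(polymer_id = c("A1", "A2"), d1 = c(1, 2), d2 = c(4, 6))
  write.csv(df3, path, row.names = FALSE)
  expect_message(tab <- read_descriptor_table(path), "2 polymers x 2")
  expect_equal(dim(tab), c(2L, 2L))
})

test_that("the shipped descriptor schema loads and tags the canonical set", {
  path <- system.file("extdata", "descriptor_schema.yaml",
                      package = "pbaescreen")
  schema <- read_descriptor_schema(path)
  tags <- unlist(schema)
  expect_setequal(unique(tags),
                  c("amine", "acrylate", "repeat_unit", "experimental"))
  expect_true(all(c("poly_zeta_potential", "repeat_pKa",
                    "poly_diffusion_coefficient") %in% names(schema)))
})

test_that("standardization z-scores columns and is idempotent", {
  # closed form: column (1, 2, 3) has sd exactly 1
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20), const = c(5, 5, 5))
  expect_warning(standardize_descriptors(m), "constant")
  std <- suppressWarnings(standardize_descriptors(m))
  expect_equal(std$z_values[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(std$dropped_constant, "const")

  set.seed(11)
  m2 <- matrix(rnorm(60, mean = 5, sd = 3), 10, 6,
               dimnames = list(NULL, paste0("d", 1:6)))
  z <- standardize_descriptors(m2)$z_values
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  # idempotence
  z2 <- standardize_descriptors(z)$z_values
  expect_equal(unname(z2), unname(z), tolerance = 1e-12)
})

test_that("constant columns do not affect distances once standardized", {
  set.seed(12)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("d", 1:5)))
  with_const <- cbind(m, flat = rep(2, 8))
  d1 <- manhattan_distances(standardize_descriptors(m))
  d2 <- manhattan_distances(
    suppressWarnings(standardize_descriptors(with_const)))
  expect_equal(d1$values, d2$values, ignore_attr = TRUE)
})

test_that("validation reports planted correlation structure", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 2))
  rep1 <- validate_library(descriptor_table(m, paste0("A", 1:4)))
  expect_equal(nrow(rep1$high_correlations), 1L)
  expect_equal(rep1$high_correlations$r[1], 1.0)

  clean <- validate_library(descriptor_table(
    matrix(c(1, 5, 2, 9, 3, 4), 3, 2, dimnames = list(NULL, c("a", "b"))),
    paste0("A", 1:3)))
  expect_true(clean$clean)

  # planted block correlation 0.9 is recovered at threshold 0.8
  lib <- generate_library(library_sim_config(
    n_amines = 50, n_acrylates = 4, block_correlation = 0.9))
  rep2 <- validate_library(lib$descriptors, cor_threshold = 0.8)
  blk <- lib$truth$descriptor_block
  nm <- lib$descriptors$descriptor_names
  pair_blocks <- cbind(blk[match(rep2$high_correlations$descriptor_a, nm)],
                       blk[match(rep2$high_correlations$descriptor_b, nm)])
  # every reported pair is within-block, and most within-block pairs appear
  expect_true(all(pair_blocks[, 1] == pair_blocks[, 2]))
  n_within <- sum(outer(blk, blk, "==")[upper.tri(diag(length(blk)))])
  expect_gt(nrow(rep2$high_correlations) / n_within, 0.9)
})
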