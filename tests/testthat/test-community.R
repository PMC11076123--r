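test_that("haemocytometer scale-up matches hand arithmetic and floors", {
  expect_identical(estimate_population(10, 0.8, 150), 1875L)
  expect_identical(estimate_population(0, 0.8, 150), 0L)
  expect_identical(estimate_population(0, 3.2, 30), 0L)
  expect_identical(estimate_population(7, 3.2, 30), 65L) # floor(65.625)
  # vectorised
  expect_identical(estimate_population(c(10, 7), c(0.8, 3.2), c(150, 30)),
                   c(1875L, 65L))
})

test_that("scale-up rejects invalid observations", {
  expect_error(estimate_population(-1, 0.8, 150), "non-negative")
  expect_error(estimate_population(2.5, 0.8, 150), "non-negative integers")
  expect_error(estimate_population(1, 0, 150), "positive")
  expect_error(estimate_population(1, 0.8, -30), "positive")
  expect_error(estimate_population(1, 32, 30), "must not exceed")
})

test_that("scale-up is monotone and never exceeds the unrounded estimate", {
  set.seed(101)
  for (i in 1:50) {
    raw <- sample(0:500, 1)
    cv <- sample(c(0.8, 3.2), 1)
    sv <- sample(c(30, 150), 1)
    est <- estimate_population(raw, cv, sv)
    expect_lte(est, raw * sv / cv + 1e-6)
    expect_gte(est, raw) # suspension >= counted volume
    expect_gte(estimate_population(raw + 1, cv, sv), est)
    expect_gte(estimate_population(raw, cv, sv * 2), est)
  }
})

test_that("composition construction normalises and validates", {
  cc <- community_composition(c(a = 3, b = 1))
  expect_s3_class(cc, "community_composition")
  expect_equal(sum(cc$proportions), 1, tolerance = 1e-12)
  expect_equal(cc$proportions, c(0.75, 0.25))
  expect_error(community_composition(c(a = -1, b = 2)), "non-negative")
  expect_error(community_composition(c(0, 0)), "positive sum")
  expect_error(community_composition(c(a = 1, a = 1)), "unique")
  # unnamed vectors get placeholder group names
  expect_length(community_composition(c(1, 1))$species_groups, 2)
})

test_that("long count files are read, filled and validated", {
  path <- write_tmp_table(tiny_long_df())
  s <- read_samples(path)
  expect_equal(nrow(s), 2)
  expect_setequal(s$individual_id, c("w1", "n1"))
  w <- s[s$individual_id == "w1", ]
  expect_identical(w$total, 500L)
  expect_identical(w$Trichonympha_agilis, 400L)
  # groups absent from the file are zero-filled
  expect_identical(w$Pyrsonympha_spp, 0L)

  bad <- tiny_long_df()
  bad$caste_group[1] <- "soldier"
  expect_error(read_samples(write_tmp_table(bad)), "soldier")

  bad <- tiny_long_df()
  bad$species_group[3] <- "Mystery_protist"
  expect_error(read_samples(write_tmp_table(bad)), "Mystery_protist")

  dup <- rbind(tiny_long_df(), tiny_long_df()[1, ])
  expect_error(read_samples(write_tmp_table(dup)), "duplicate")

  dec <- tiny_long_df()
  dec$count[2] <- 1.5
  expect_error(read_samples(write_tmp_table(dec)), "non-negative integers")
})

test_that("raw-count dialect applies the scale-up row-wise", {
  df <- tiny_long_df()
  df$count <- NULL
  df$raw_count <- c(12L, 3L, 5L, 1L)
  # defaults: large groups 3.2 ul; worker suspension 150 ul, nymph 30 ul
  path <- write_tmp_table(df, ext = "tsv")
  s <- read_samples(path)
  w <- s[s$individual_id == "w1", ]
  n <- s[s$individual_id == "n1", ]
  expect_identical(w$Trichonympha_agilis, estimate_population(12, 3.2, 150))
  expect_identical(w$Teranympha_mirabilis, estimate_population(3, 3.2, 150))
  expect_identical(n$Trichonympha_agilis, estimate_population(5, 3.2, 30))
  expect_identical(n$Teranympha_mirabilis, estimate_population(1, 3.2, 30))

  # explicit volume columns override the defaults
  df$counted_volume <- 0.8
  df$suspension_volume <- 30
  s2 <- read_samples(write_tmp_table(df, ext = "tsv"))
  expect_identical(s2$Trichonympha_agilis[s2$individual_id == "w1"],
                   estimate_population(12, 0.8, 30))
})

test_that("write -> read round-trip preserves every field exactly", {
  sim <- generate_dataset(synthetic_config(
    n_per_caste = c(worker = 3, nymph = 3, A7 = 2)), seed = 7)
  path <- tempfile(fileext = ".csv")
  write_samples(sim$samples, path)
  back <- read_samples(path)
  expect_identical(back, sim$samples)
})

test_that("composition write -> read round-trip keeps proportions and source", {
  cc <- default_compositions()$nymph
  path <- tempfile(fileext = ".tsv")
  write_composition(cc, path)
  back <- read_composition(path)
  expect_equal(back$proportions, cc$proportions, tolerance = 1e-12)
  expect_identical(back$species_groups, cc$species_groups)
  expect_identical(back$source, cc$source)
})

test_that("individual-mean averaging matches hand arithmetic and an oracle", {
  panel <- default_species_groups()$name
  s <- tiny_wide_samples(c(10, 10), caste = "nymph")
  s[1, panel] <- c(5L, 5L, rep(0L, 8))   # proportions (0.5, 0.5, ...)
  s[2, panel] <- c(9L, 1L, rep(0L, 8))   # proportions (0.9, 0.1, ...)
  s$total <- as.integer(rowSums(s[, panel]))
  avg <- average_composition(s, "nymph")
  expect_equal(avg$proportions[1:2], c(0.7, 0.3), tolerance = 1e-12)

  # single individual: its own proportion vector
  one <- average_composition(s[1, , drop = FALSE], "nymph")
  expect_equal(one$proportions[1:2], c(0.5, 0.5), tolerance = 1e-12)

  # random counts vs an independently coded spreadsheet-style mean
  set.seed(33)
  r <- tiny_wide_samples(rep(0, 3), caste = "worker", prefix = "w")
  for (i in 1:3) r[i, panel] <- as.integer(rpois(10, 40) + 1)
  r$total <- as.integer(rowSums(r[, panel]))
  oracle <- rep(0, 10)
  for (i in 1:3) oracle <- oracle + unlist(r[i, panel]) / r$total[i]
  oracle <- oracle / 3
  avg_r <- average_composition(r, "worker")
  expect_equal(avg_r$proportions, unname(oracle / sum(oracle)),
               tolerance = 1e-12)

  # permutation equivariance in sample order
  perm <- average_composition(r[c(3, 1, 2), ], "worker")
  expect_equal(perm$proportions, avg_r$proportions, tolerance = 1e-12)
})

test_that("pooled averaging weights individuals by abundance", {
  panel <- default_species_groups()$name
  s <- tiny_wide_samples(c(0, 0), caste = "worker")
  s[1, panel] <- c(90L, 10L, rep(0L, 8))
  s[2, panel] <- c(1L, 9L, rep(0L, 8))
  s$total <- as.integer(rowSums(s[, panel]))
  pooled <- average_composition(s, "worker", method = "pooled")
  expect_equal(pooled$proportions[1:2], c(91, 19) / 110, tolerance = 1e-12)
})

test_that("averaging rejects empty filters and zero-total individuals", {
  s <- tiny_wide_samples(c(100, 200), caste = "A2")
  expect_error(average_composition(s, "worker"), "no samples match")
  expect_error(average_composition(s, "A2", colonies = "IX"), "no samples match")
  s$total[1] <- 0L
  s[1, species_columns(s)] <- 0L
  expect_error(average_composition(s, "A2"), "a1")
})
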