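model <- default_energy_model()

test_that("the shipped energy model satisfies its structural constraints", {
  wc <- c("AU", "UA", "CG", "GC")
  expect_true(all(model$stack[wc, wc] < 0))
  expect_true(all(model$bulge >= 0))
  expect_true(all(model$internal >= 0))
  expect_gte(model$max_loop, 1)
  # symmetry of the WC block: stack(p1,p2) == stack(flip(p2),flip(p1))
  flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG")
  for (p1 in wc) for (p2 in wc) {
    expect_equal(model$stack[p1, p2], model$stack[flip[p2], flip[p1]],
                 label = paste(p1, p2))
  }
})

test_that("a fully complementary duplex sums initiation plus stacks", {
  # 4 GC pairs, 3 GG/CC stacks, no AU/GU ends
  d <- duplex_mfe("GGGG", "CCCC", model)
  expected <- model$init_dG + 3 * model$stack["GC", "GC"]
  expect_equal(d$mfe, expected, tolerance = 1e-9)
  expect_equal(nrow(d$pairing), 4)
  # pairing is antiparallel and non-crossing: miRNA up, target down
  expect_identical(d$pairing$mirna_pos, 0:3)
  expect_identical(d$pairing$target_pos, 3:0)
  # terminal AU penalty applies at both helix ends
  d2 <- duplex_mfe("AGGA", "UCCU", model)
  expected2 <- model$init_dG + 2 * model$au_end_dG +
    model$stack["AU", "GC"] + model$stack["GC", "GC"] + model$stack["GC", "AU"]
  expect_equal(d2$mfe, expected2, tolerance = 1e-9)
})

test_that("non-complementary sequences return the unstable sentinel", {
  d <- duplex_mfe("AAAA", "AAAA", model)
  expect_equal(d$mfe, 0)
  expect_equal(nrow(d$pairing), 0)
  expect_error(duplex_mfe("ANAA", "UUUU", model))
  expect_error(duplex_mfe("A", "UUUU", model))
})

test_that("DP agrees with the independent reference implementation", {
  set.seed(4)
  for (i in 1:15) {
    a <- rand_rna(sample(2:8, 1))
    b <- rand_rna(sample(2:8, 1))
    expect_equal(duplex_mfe(a, b, model)$mfe, duplex_mfe_reference(a, b, model),
                 tolerance = 1e-9, label = paste(a, b))
  }
  for (i in 1:20) {
    a <- rand_rna(sample(9:12, 1))
    b <- rand_rna(sample(9:12, 1))
    expect_equal(duplex_mfe(a, b, model)$mfe, duplex_mfe_reference(a, b, model),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("the reference itself matches exhaustive enumeration on short inputs", {
  set.seed(5)
  for (i in 1:12) {
    a <- rand_rna(sample(2:6, 1))
    b <- rand_rna(sample(2:6, 1))
    expect_equal(duplex_mfe_reference(a, b, model),
                 clearclipr:::duplex_enum_mfe(a, b, model),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("extending a perfect helix never raises the MFE", {
  set.seed(6)
  for (i in 1:10) {
    core_m <- rand_rna(8)
    core_t <- rc_oracle(chartr("U", "T", core_m))
    core_t <- chartr("T", "U", core_t)
    m1 <- duplex_mfe(core_m, core_t, model)$mfe
    ext_m <- paste0("G", core_m)
    ext_t <- paste0(core_t, "C")
    m2 <- duplex_mfe(ext_m, ext_t, model)$mfe
    expect_lte(m2, m1 + 1e-9)
  }
})

test_that("shuffled_null is a derangement preserving both multisets", {
  set.seed(2)
  ints <- tibble::tibble(
    mirna_id = sample(sprintf("miR-%d", 1:10), 200, replace = TRUE),
    target_seq = rand_dna(200, 30))
  out <- shuffled_null(ints, seed = 2)
  expect_true(all(out$mirna_id != out$mirna_id_original))
  expect_identical(sort(out$mirna_id), sort(ints$mirna_id))
  expect_identical(out$target_seq, ints$target_seq)
  # two interactions with distinct miRNAs: swap is forced
  two <- tibble::tibble(mirna_id = c("A", "B"), target_seq = c("ACGT", "TTTT"))
  sw <- shuffled_null(two, seed = 1)
  expect_identical(sw$mirna_id, c("B", "A"))
  # single-miRNA input is an error
  one <- tibble::tibble(mirna_id = c("A", "A"), target_seq = c("AC", "GT"))
  expect_error(shuffled_null(one), class = "clearclipr_config_error")
  # different seeds give different assignments
  expect_false(identical(shuffled_null(ints, seed = 3)$mirna_id,
                         out$mirna_id))
})

test_that("energy gap statistics behave under null and shifted inputs", {
  set.seed(3)
  x <- rnorm(200, -10, 3)
  g0 <- energy_gap(x, x, n_perm = 500, seed = 1)
  expect_equal(g0$delta_mean, 0)
  expect_gt(g0$p_mean, 0.9)
  g1 <- energy_gap(x - 2, x, n_perm = 500, seed = 1)
  expect_equal(g1$delta_median, -2, tolerance = 1e-9)
  expect_equal(g1$delta_mean, -2, tolerance = 1e-9)
  expect_lt(g1$p_mean, 0.01)
  expect_s3_class(glance(g1), "tbl_df")
})

test_that("planted canonical complementarity gives a negative energy gap", {
  set.seed(9)
  n <- 120
  mir <- rand_dna(15, 22)
  pick <- sample(15, n, replace = TRUE)
  targets <- vapply(pick, function(i) {
    paste0(rand_dna(1, 12), rc_oracle(substr(mir[i], 1, 9)), rand_dna(1, 12))
  }, character(1))
  pairs <- tibble::tibble(mirna_id = sprintf("m%02d", pick),
                          mirna_seq = mir[pick], target_seq = targets)
  real <- duplex_energies(pairs, model)
  nul <- shuffled_null(pairs, seed = 4)
  nul$mirna_seq <- mir[as.integer(substr(nul$mirna_id, 2, 3))]
  null_e <- duplex_energies(nul, model)
  gap <- energy_gap(real$mfe, null_e$mfe, n_perm = 2000, seed = 5)
  expect_lt(gap$delta_mean, 0)
  expect_lt(gap$p_mean, 0.01)
})
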