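test_that("AF threshold estimation is an inverse-ECDF quantile of qualifying variants", {
  # degenerate distribution: any quantile returns the common value
  expect_equal(estimate_af_threshold(rep(0.5, 8), rep(0.01, 8), 0.43, 0.5),
               0.01)
  expect_equal(estimate_af_threshold(rep(0.5, 8), rep(0.01, 8), 0.43, 0.99),
               0.01)
  # 90 low + 10 high at the 0.95 quantile
  ds <- rep(0.9, 100)
  af <- c(rep(0.001, 90), rep(0.1, 10))
  expect_equal(estimate_af_threshold(ds, af, 0.43, 0.95), 0.1)
  # only DS >= ds_t variants qualify (inclusive)
  ds2 <- c(rep(0.43, 3), rep(0.1, 97))
  af2 <- c(rep(0.2, 3), rep(0.9, 97))
  expect_equal(estimate_af_threshold(ds2, af2, 0.43, 0.95), 0.2)
  expect_error(estimate_af_threshold(rep(0.1, 5), rep(0.5, 5), 0.43),
               class = "mitotier_estimation_error")
  # determinism
  expect_identical(estimate_af_threshold(ds, af, 0.43, 0.95),
                   estimate_af_threshold(ds, af, 0.43, 0.95))
})

test_that("tier assignment follows the published per-class rules", {
  expect_equal(assign_tier(0.50, 0.001, "tRNA"), "Pathogenic")
  expect_equal(assign_tier(0.20, 0.01, "non-synonymous"), "Polymorphic")
  expect_equal(assign_tier(0.50, 0.01, "tRNA"), "Likely Pathogenic")
  expect_equal(assign_tier(0.20, 0.001, "non-synonymous"),
               "Likely Polymorphic")
  # boundary: both operators are inclusive
  expect_equal(assign_tier(0.43, 0.003264, "non-synonymous"), "Pathogenic")
  expect_equal(assign_tier(0.35, 0.005020, "tRNA"), "Pathogenic")
  # just past the boundary on either axis
  expect_equal(assign_tier(0.4299999, 0.003264, "non-synonymous"),
               "Likely Polymorphic")
  expect_equal(assign_tier(0.43, 0.0032641, "non-synonymous"),
               "Likely Pathogenic")
})

test_that("VUS overrides and unassigned DS is Unclassified", {
  expect_equal(assign_tier(0.9, 0.0001, "tRNA", vus = TRUE), "VUS")
  expect_equal(assign_tier(NA_real_, 0.0001, "tRNA", vus = TRUE), "VUS")
  expect_equal(assign_tier(NA_real_, 0.2, "non-synonymous"), "Unclassified")
  expect_error(assign_tier(0.5, NA_real_, "tRNA"),
               class = "mitotier_input_error")
  expect_error(assign_tier(0.5, 0.1, "rRNA"),
               class = "mitotier_domain_error")
})

test_that("the four quadrants partition the unit square for both threshold sets", {
  grid <- expand.grid(ds = seq(0, 1, by = 0.01), af = seq(0, 1, by = 0.01))
  th <- threshold_config()
  for (cls in c("non-synonymous", "tRNA")) {
    tier <- assign_tier(grid$ds, grid$af, cls, thresholds = th)
    expect_true(all(tier %in% c("Pathogenic", "Likely Pathogenic",
                                "Likely Polymorphic", "Polymorphic")))
    ds_t <- if (cls == "tRNA") th$ds_t_trna else th$ds_t_nonsyn
    af_t <- if (cls == "tRNA") th$af_t_trna else th$af_t_nonsyn
    # each point satisfies exactly one quadrant predicate
    hits <- cbind(grid$ds >= ds_t & grid$af <= af_t,
                  grid$ds >= ds_t & grid$af > af_t,
                  grid$ds < ds_t & grid$af <= af_t,
                  grid$ds < ds_t & grid$af > af_t)
    expect_true(all(rowSums(hits) == 1))
    expect_equal(tier,
                 c("Pathogenic", "Likely Pathogenic", "Likely Polymorphic",
                   "Polymorphic")[max.col(hits)])
  }
})

test_that("tiers are monotone in DS and AF = 0 never yields Likely Pathogenic", {
  side <- function(tier) ifelse(tier %in% c("Pathogenic",
                                            "Likely Pathogenic"), 1, 0)
  set.seed(3)
  for (cls in c("non-synonymous", "tRNA")) {
    af <- runif(200)
    ds_lo <- runif(200)
    ds_hi <- pmin(ds_lo + runif(200), 1)
    expect_true(all(side(assign_tier(ds_hi, af, cls)) >=
                      side(assign_tier(ds_lo, af, cls))))
    # potential variants (AF = 0) with DS over threshold are Pathogenic
    expect_true(all(assign_tier(seq(0.43, 1, 0.01), 0,
                                "non-synonymous") == "Pathogenic"))
    expect_true(all(assign_tier(seq(0.35, 1, 0.01), 0, "tRNA") ==
                      "Pathogenic"))
  }
})

test_that("threshold configuration files override defaults", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# custom operating point",
               "ds_t_nonsyn = 0.5",
               "af_quantile = 0.9",
               "trna_weights = 1,1,1,1,1,1,1,1,1"), path)
  cfg <- read_threshold_config(path)
  expect_equal(cfg$thresholds$ds_t_nonsyn, 0.5)
  expect_equal(cfg$thresholds$ds_t_trna, 0.35)     # untouched default
  expect_equal(cfg$thresholds$af_quantile, 0.9)
  expect_equal(unname(normalize_weights(cfg$trna_weights)), rep(1 / 9, 9))
  writeLines("nonsense = 1", path)
  expect_error(read_threshold_config(path), class = "mitotier_config_error")
  expect_error(threshold_config(ds_t_nonsyn = 1.4),
               class = "mitotier_domain_error")
})
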