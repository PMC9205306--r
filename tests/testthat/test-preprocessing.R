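make_raw <- function() {
  data.frame(
    species_id = c("sp1", "sp1", "sp2"),
    leaf_area = c(30, 40, 20),
    leaf_dry_weight = c(0.1, 0.2, 0.1),
    leaf_wet_weight = c(0.2, 0.5, 0.3),
    wood_dry_weight = c(0.5, 0.5, 0.2),
    wood_wet_volume = c(1.25, 1.25, 1),
    stem_dry_weight = c(1, 1, 0.5),
    stem_wet_weight = c(2, 2, 1.5),
    root_length = c(2, 2, 1),
    root_dry_weight = c(0.2, 0.2, 0.1))
}

test_that("traits follow their defining formulas and species means are taken", {
  tab <- derive_traits(make_raw())
  # sp2 single seedling: direct formula values
  expect_equal(tab$values["sp2", "SLA"], 20 / 0.1)     # area / dry weight
  expect_equal(tab$values["sp2", "LWC"], (0.3 - 0.1) / 0.1)
  expect_equal(tab$values["sp2", "WD"], 0.2 / 1)
  expect_equal(tab$values["sp2", "SWC"], (1.5 - 0.5) / 0.5)
  expect_equal(tab$values["sp2", "SRL"], 1 / 0.1)
  # sp1: mean over the two seedlings' per-seedling values
  expect_equal(tab$values["sp1", "SLA"], mean(c(30 / 0.1, 40 / 0.2)))
  expect_equal(tab$values["sp1", "LWC"], mean(c(1, 1.5)))
  # canonical worked examples
  expect_equal(tab$values["sp1", "WD"], 0.4)           # 0.5 g / 1.25 cm^3
  # biomass = summed dry organ masses
  expect_equal(tab$biomass[["sp2"]], 0.1 + 0.5 + 0.1)
})

test_that("zero denominators become missing cells with a warning", {
  raw <- make_raw()
  raw$leaf_dry_weight[3] <- 0
  # both SLA and LWC lose their denominator: two warnings
  expect_warning(expect_warning(tab <- derive_traits(raw), "zero denominator"))
  expect_true(is.na(tab$values["sp2", "SLA"]))
  raw2 <- make_raw()
  raw2$leaf_dry_weight[3] <- 0.4   # dry > wet
  expect_warning(derive_traits(raw2), "dry weight exceeds")
  raw3 <- make_raw()
  raw3$leaf_area[1] <- -1
  expect_error(derive_traits(raw3), "negative")
})

test_that("log transform applies log10 to listed traits only, with state tracking", {
  x <- cbind(A = c(100, 10, 1, 1000, 10, 100, 10, 1),
             B = c(1, 2, 3, 4, 5, 6, 7, 8))
  tab <- trait_table(x, species_id = paste0("s", 1:8))
  tr <- log_transform(tab, "A")
  expect_equal(unname(tr$values[1, "A"]), 2)           # log10(100)
  expect_equal(tr$values[, "B"], tab$values[, "B"])
  expect_equal(unname(tr$state), c("log10", "raw"))
  # empty transform list: identity
  expect_identical(log_transform(tab, character())$values, tab$values)
  # normality report is attached and advisory
  rep <- attr(tr, "normality")
  expect_true(all(c("W_before", "p_after", "transformed") %in% names(rep)))
  # non-positive value in a listed trait names species and trait
  x2 <- x; x2[3, "A"] <- 0
  tab2 <- trait_table(x2, species_id = paste0("s", 1:8))
  expect_error(log_transform(tab2, "A"), "s3")
  # refuses to transform twice
  expect_error(log_transform(tr, "A"), "refusing")
})

test_that("size correction residualizes significant traits and is exactly orthogonal", {
  set.seed(42)
  n <- 50
  b <- 10^rnorm(n, 0, 0.5)
  perfect <- 2 * log10(b)                       # exact fit: residuals ~ 0
  planted <- 1 * log10(b) + rnorm(n, 0, 0.5)    # beta = 1, sigma = 0.5
  flat <- rnorm(n)
  tab <- trait_table(cbind(perfect = perfect, planted = planted, flat = flat),
                     species_id = paste0("s", 1:n), biomass = b)
  out <- suppressWarnings(size_correct(tab))  # lm warns on the exact fit
  rep <- attr(out, "size_correction")
  expect_equal(rep$decision[rep$trait == "perfect"], "residualized")
  expect_lt(max(abs(out$values[, "perfect"])), 1e-9)
  expect_equal(rep$decision[rep$trait == "planted"], "residualized")
  # OLS residuals orthogonal to the regressor at machine precision
  expect_lt(abs(cor(out$values[, "planted"], log10(b))), 1e-9)
  expect_lt(abs(sum(out$values[, "planted"] * log10(b))), 1e-8)
  expect_error(size_correct(out), "refusing")
})

test_that("size-correction decision has the designed type-I error and skips tiny traits", {
  kept <- vapply(1:200, function(s) {
    set.seed(s)
    b <- 10^rnorm(200, 0, 0.5)
    tab <- trait_table(cbind(t1 = rnorm(200)), species_id = paste0("s", 1:200),
                       biomass = b)
    attr(size_correct(tab), "size_correction")$decision == "kept"
  }, logical(1))
  expect_gte(mean(kept), 0.90)   # slope test at alpha = 0.05

  tab <- trait_table(cbind(t1 = c(1, 2, NA, NA, NA)),
                     species_id = paste0("s", 1:5), biomass = rep(1, 5))
  expect_warning(out <- size_correct(tab), "skipped")
  expect_equal(attr(out, "size_correction")$decision, "skipped")
})

test_that("preprocessing commutes with row permutation of species", {
  set.seed(7)
  n <- 30
  b <- 10^rnorm(n, 0, 0.5)
  x <- cbind(A = 10^rnorm(n), B = rnorm(n) + log10(b))
  sp <- sprintf("s%02d", 1:n)
  tab <- trait_table(x, species_id = sp, biomass = b)
  perm <- sample(n)
  tabp <- trait_table(x[perm, ], species_id = sp[perm], biomass = b[perm])
  f <- function(t) size_correct(log_transform(t, "A"))
  expect_equal(f(tab)$values[sp, ], f(tabp)$values[sp, ])
})
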