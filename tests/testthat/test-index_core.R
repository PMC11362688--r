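reg <- default_registry()

test_that("orientation complements adverse incidences", {
  expect_equal(orient(8.0, "adverse_incidence"), 92.0)
  expect_equal(orient(11.2, "adverse_incidence"), 88.8)
  expect_equal(orient(0, "adverse_incidence"), 100)
  expect_equal(orient(73.5, "coverage"), 73.5)
  expect_error(orient(105, "coverage"), "105")
})

test_that("geometric mean matches the direct log-sum oracle", {
  expect_equal(geometric_mean(c(50, 50, 50)), 50)
  expect_equal(geometric_mean(c(25, 100)), 50)
  # published domain medians, expected value frozen from oracle_gm()
  expect_equal(geometric_mean(c(64.8, 82.8, 9.8, 54.9, 66.6)),
               45.370712, tolerance = 1e-6)
  expect_equal(geometric_mean(c(64.8, 82.8, 9.8, 54.9, 66.6)),
               oracle_gm(c(64.8, 82.8, 9.8, 54.9, 66.6)))
  expect_error(geometric_mean(numeric(0)), "empty")
  # the floor keeps zeros from annihilating the mean
  expect_equal(geometric_mean(c(0, 100), floor = 0.1), sqrt(10))
})

test_that("index attains its bounds and is constant on constants", {
  d100 <- make_districts(4, 100)
  r <- compute_indices(d100, reg)
  expect_equal(r$uhcd, rep(100, 4))
  expect_equal(r$service_coverage, rep(100, 4))
  expect_equal(r$financial_risk_protection, rep(100, 4))

  for (method in c("geometric", "arithmetic")) {
    rc <- compute_indices(make_districts(3, 37.2), reg,
                          aggregation_spec(method))
    expect_equal(rc$uhcd, rep(37.2, 3), tolerance = 1e-10)
  }
})

test_that("the near-zero cancer-screening district matches the hand oracle", {
  d <- make_districts(3, 50)
  d$cervical_screening <- 0.5
  d$breast_screening <- 0.5
  r <- compute_indices(d, reg)
  expect_equal(r$area_cancer[1], 0.5, tolerance = 1e-10)
  expect_equal(r$domain_ncd[1], 15.811388, tolerance = 1e-6)
  # geometric mean over all FIVE domains (frozen from oracle_gm)
  expect_equal(r$uhcd[1], 39.716412, tolerance = 1e-6)
  ncd_oracle <- oracle_gm(c(50, 50, 50, oracle_gm(c(0.5, 0.5))))
  expect_equal(r$uhcd[1], oracle_gm(c(50, 50, 50, ncd_oracle, 50)))
})

test_that("missing indicators are named in the error", {
  d <- make_districts(3, 50)
  d$tb_treatment[2] <- NA
  err <- expect_error(compute_indices(d, reg))
  expect_match(conditionMessage(err), "tb_treatment")
  expect_match(conditionMessage(err), "d002")
})

test_that("terciles split 687 distinct districts into 229/229/229", {
  set.seed(1)
  v <- setNames(sample(seq_len(687)), sprintf("d%03d", 1:687))
  t3 <- classify_terciles(v)
  expect_equal(unname(table(t3)[c("low", "medium", "high")]),
               as.integer(c(229, 229, 229)), ignore_attr = TRUE)
  # ordering respected: every low value below every high value
  expect_lt(max(v[t3 == "low"]), min(v[t3 == "high"]))
})

test_that("tercile remainder goes to the lowest groups, ties by id", {
  v6 <- setNames(c(4, 2, 6, 1, 5, 3), paste0("d", 1:6))
  expect_equal(unname(table(classify_terciles(v6))[c("low", "medium", "high")]),
               as.integer(c(2, 2, 2)), ignore_attr = TRUE)
  v7 <- setNames(7:1, paste0("d", 1:7))
  t7 <- classify_terciles(v7)
  expect_equal(sum(t7 == "low"), 3)
  expect_equal(sum(t7 == "medium"), 2)
  expect_equal(sum(t7 == "high"), 2)
  # ties broken lexicographically by district id
  vt <- setNames(c(1, 1, 1), c("b", "a", "c"))
  tt <- classify_terciles(vt)
  expect_equal(unname(tt[c("a", "b", "c")]), c("low", "medium", "high"))
  expect_error(classify_terciles(c(a = 1, b = 2)), ">= 3")
})

test_that("summaries report medians, spread and threshold shares", {
  # single district: median is the value, SD reported as 0
  res1 <- data.frame(district_id = "d1", state_id = "s", uhcd = 61.5,
                     service_coverage = 61.5,
                     financial_risk_protection = 61.5,
                     domain_rmnch = 61.5, stringsAsFactors = FALSE)
  s1 <- summarize_index(res1)
  expect_equal(s1$table$median[1], 61.5)
  expect_equal(s1$table$sd[1], 0)

  # values 1..100, threshold 50: 50/100 above
  res <- data.frame(district_id = paste0("d", 1:100),
                    state_id = "s", uhcd = 1:100,
                    service_coverage = 1:100,
                    financial_risk_protection = 1:100)
  s <- summarize_index(res, threshold = 50)
  expect_equal(s$above$n_above, 50)
  expect_equal(s$above$percentage, 50.0)

  # 145 of 687 above: 21.1%
  res2 <- data.frame(district_id = sprintf("d%03d", 1:687), state_id = "s",
                     uhcd = c(rep(60, 145), rep(40, 542)),
                     service_coverage = 50,
                     financial_risk_protection = 50)
  s2 <- summarize_index(res2, threshold = 50)
  expect_equal(s2$above$n_above, 145)
  expect_equal(s2$above$percentage, 21.1)
})

test_that("index properties: bounds, AM-GM, monotonicity, permutation, decomposition", {
  for (seed in c(2, 17, 101)) {
    d <- make_random_districts(15, seed = seed)
    g <- compute_indices(d, reg, aggregation_spec("geometric"))
    a <- compute_indices(d, reg, aggregation_spec("arithmetic"))
    f <- compute_indices(d, reg, aggregation_spec("flat_geometric"))

    expect_true(all(g$uhcd >= 0.1 & g$uhcd <= 100))
    # AM >= GM at every level, strict when values differ
    expect_true(all(g$uhcd <= a$uhcd + 1e-12))
    expect_true(all(g$uhcd < a$uhcd))

    # raising one oriented indicator never lowers the index
    d2 <- d
    d2$anc4 <- pmin(d2$anc4 + 5, 100)
    g2 <- compute_indices(d2, reg)
    expect_true(all(g2$uhcd >= g$uhcd - 1e-12))
    d3 <- d
    d3$cat_expenditure <- pmax(d3$cat_expenditure - 5, 0)  # lower incidence
    g3 <- compute_indices(d3, reg)
    expect_true(all(g3$uhcd >= g$uhcd - 1e-12))

    # decomposition: uhcd = (sc^4 * frp)^(1/5)
    expect_equal(g$uhcd,
                 (g$service_coverage^4 * g$financial_risk_protection)^(1 / 5),
                 tolerance = 1e-10)

    # flat differs from hierarchical when areas have unequal sizes
    expect_true(all(abs(f$uhcd - g$uhcd) > 1e-8))
  }
})

test_that("indicator and area order never changes any score", {
  d <- make_random_districts(8, seed = 23)
  base <- compute_indices(d, reg)
  # rebuild the registry with reversed indicator/area/domain order
  cfg <- yaml::read_yaml(system.file("extdata", "registry_default.yaml",
                                     package = "uhcd"))
  cfg$domains <- rev(lapply(cfg$domains, function(dom) {
    dom$areas <- rev(lapply(dom$areas, function(a) {
      a$indicators <- rev(a$indicators); a
    }))
    dom
  }))
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, p)
  rev_reg <- load_registry(p)
  r2 <- compute_indices(d, rev_reg)
  expect_equal(r2$uhcd, base$uhcd, tolerance = 1e-12)
  expect_equal(r2$domain_ncd, base$domain_ncd, tolerance = 1e-12)
  expect_equal(r2$area_cancer, base$area_cancer, tolerance = 1e-12)
})

test_that("compute_index single-district wrapper agrees with the table path", {
  d <- make_random_districts(1, seed = 31)
  vals <- unlist(d[1, reg$indicators$id])
  single <- compute_index(vals, reg)
  tab <- compute_indices(rbind(d, d, d), reg)[1, ]
  expect_equal(single$uhcd, tab$uhcd)
  expect_equal(unname(single$domain_scores["frp"]), tab$domain_frp)
})
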