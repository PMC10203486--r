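test_that("transformation tables load, cross-check and derive groups", {
  p <- write_fixture(c("name\texact_mass\tformula",
                       "glycine_residue\t57.02146\tC2H3NO",
                       "water\t18.010565\tH2O"))
  tf <- load_transformations(p)
  expect_identical(nrow(tf), 2L)
  expect_identical(tf$group, c(3L, 4L))  # N+O; O-only

  # mass inconsistent with its formula by > 1 mDa is rejected by name
  bad <- write_fixture(c("name\texact_mass\tformula",
                         "glycine_residue\t57.0250\tC2H3NO"))
  expect_error(load_transformations(bad), "glycine_residue")

  expect_error(load_transformations(write_fixture("name\texact_mass")),
               "empty")
  dup <- write_fixture(c("name\texact_mass", "x\t10.5", "x\t11.5"))
  expect_error(load_transformations(dup), "duplicate")
  neg <- write_fixture(c("name\texact_mass", "x\t-1"))
  expect_error(load_transformations(neg), "positive")
})

test_that("the shipped transformation table is internally consistent", {
  tf <- default_transformations()
  expect_gte(nrow(tf), 40L)
  f <- parse_formula(tf$formula)
  expect_true(all(abs(monoisotopic_mass(f) - tf$exact_mass) < 1e-3))
  expect_identical(tf$group, hetero_group(f))
  expect_true("glyoxylate" %in% tf$name)
  expect_true("adenine" %in% tf$name)
  expect_true("allantoin" %in% tf$name)
})

test_that("hetero groups follow the S / N / N+O / O taxonomy", {
  f <- parse_formula(c("C3H5NOS", "C5H5N5", "C2H3NO", "H2O", "CH2"))
  expect_identical(hetero_group(f), c(1L, 2L, 3L, 4L, NA_integer_))
})

test_that("edges appear exactly when a mass difference matches", {
  tf <- data.frame(name = "glycine_residue", exact_mass = 57.02146,
                   group = 3L)
  net <- build_network(c(300.00000, 357.02146), tf, tol_ppm = 2)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$match_error_ppm, 0, tolerance = 1e-9)
  expect_equal(net$edges$delta_observed, 57.02146)

  # ~10 ppm off at the larger member: no edge at 2 ppm
  none <- build_network(c(300.0, 357.0250), tf, tol_ppm = 2)
  expect_identical(nrow(none$edges), 0L)
})

test_that("network matches the brute-force oracle and is order-invariant", {
  tf <- default_transformations()
  mzs <- withr::with_seed(17, sort(runif(60, 100, 1000)))
  # plant exact transformation pairs so the edge set is non-trivial
  mzs <- c(mzs, mzs[5] + 57.021464, mzs[9] + 135.054495, mzs[12] + 18.010565)
  net <- build_network(mzs, tf, tol_ppm = 2)
  expect_gt(nrow(net$edges), 0L)
  expect_identical(edge_keys(net), oracle_network(mzs, tf, 2))

  shuffled <- withr::with_seed(1, sample(mzs))
  expect_identical(edge_keys(build_network(shuffled, tf, tol_ppm = 2)),
                   edge_keys(net))
})

test_that("tolerance is monotone and edges are strictly upward", {
  tf <- default_transformations()
  mzs <- withr::with_seed(23, runif(80, 100, 1000))
  e1 <- edge_keys(build_network(mzs, tf, tol_ppm = 1))
  e2 <- edge_keys(build_network(mzs, tf, tol_ppm = 2))
  expect_true(all(e1 %in% e2))
  net <- build_network(mzs, tf, tol_ppm = 2)
  if (nrow(net$edges) > 0) {
    expect_true(all(net$edges$delta_observed > 0))
    expect_true(all(net$edges$mz_hi > net$edges$mz_lo))
  }
})

test_that("the absolute-mDa tolerance mode is available", {
  tf <- data.frame(name = "water", exact_mass = 18.010565, group = 4L)
  # 0.44 mDa off: outside 0.5 ppm of 318 (0.16 mDa) but inside 1 mDa
  net_ppm <- build_network(c(300, 318.0110), tf, tol_ppm = 0.5)
  net_mda <- build_network(c(300, 318.0110), tf, mode = "mda", tol_mda = 1)
  expect_identical(nrow(net_ppm$edges), 0L)
  expect_identical(nrow(net_mda$edges), 1L)
})

test_that("network summaries count and normalize transformations", {
  tf <- data.frame(name = c("tA", "tB"), exact_mass = c(50, 70),
                   group = c(1L, 4L))
  net <- build_network(c(100, 150, 200, 170), tf, tol_ppm = 2)
  # 100->150 (tA), 150->200 (tA), 100->170 (tB)
  s <- summarize_network(net)
  expect_identical(s$n_edges, 3L)
  expect_identical(s$n_distinct_transformations, 2L)
  ab <- setNames(s$abundance$abundance, s$abundance$transformation)
  expect_equal(unname(ab["tA"]), 2 / 3)
  expect_equal(unname(ab["tB"]), 1 / 3)
  expect_equal(sum(s$abundance$abundance), 1)
  expect_equal(unname(s$group_totals["1"]), 2 / 3)
  expect_equal(unname(s$group_totals["4"]), 1 / 3)

  # planted transformations are recovered exactly at zero mass error
  tf2 <- default_transformations()
  base <- c(201.1, 344.2, 518.3)
  planted <- c("glycine_residue", "adenine", "hexose_residue")
  mzs <- c(base, base + tf2$exact_mass[match(planted, tf2$name)])
  s2 <- summarize_network(build_network(mzs, tf2, tol_ppm = 2))
  expect_true(all(planted %in% s2$abundance$transformation))
})

test_that("an all-edges-in-one-group network has that group total at 1", {
  tf <- data.frame(name = "water", exact_mass = 18.010565, group = 4L)
  net <- build_network(c(100, 118.010565, 136.02113), tf, tol_ppm = 2)
  s <- summarize_network(net)
  expect_gte(s$n_edges, 2L)
  expect_equal(unname(s$group_totals["4"]), 1)
})

test_that("empty edge sets summarize to zeros, and node/edge tables round-trip", {
  tf <- data.frame(name = "water", exact_mass = 18.010565, group = 4L)
  net <- build_network(c(100, 500), tf)
  s <- summarize_network(net)
  expect_identical(s$n_edges, 0L)
  expect_true(all(s$group_totals == 0))

  tf2 <- default_transformations()
  net2 <- build_network(c(201.1, 258.121464), tf2)
  paths <- write_network_tables(net2, file.path(tempdir(), "net"))
  nodes <- read.delim(paste0(file.path(tempdir(), "net"), "_nodes.tsv"))
  edges <- read.delim(paste0(file.path(tempdir(), "net"), "_edges.tsv"))
  expect_identical(nrow(nodes), 2L)
  expect_identical(edges$transformation, "glycine_residue")
})
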