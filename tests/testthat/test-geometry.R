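test_that("torsion angles follow the IUPAC convention and match oracles", {
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
  set.seed(11)
  for (i in 1:300) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4),
                 tolerance = 1e-9)
  }
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("phi dihedrals require the full C(i-1), N, CA, C quadruple", {
  pool <- random_backbone_pool(n_conf = 2L, n_res = 4L, seed = 3L)
  phi <- compute_phi(pool, 1L, 3L)
  expect_true(phi > -180 && phi <= 180)
  rows <- vapply(list(c(2, "C"), c(3, "N"), c(3, "CA"), c(3, "C")),
                 function(a) which(pool$atoms$resno == as.integer(a[1]) &
                                     pool$atoms$elety == a[2]), integer(1))
  pts <- lapply(rows, function(r) pool$xyz[1L, (3 * r - 2):(3 * r)])
  expect_equal(phi, torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]))
  expect_error(compute_phi(pool, 1L, 1L), "preceding C")
})

test_that("karplus terms are exact cosines with cos2 = cos^2", {
  expect_equal(karplus_terms(60, 60), c(cos_term = 1, cos2_term = 1))
  expect_equal(karplus_terms(150, 60), c(cos_term = 0, cos2_term = 0),
               tolerance = 1e-12)
  expect_equal(karplus_terms(120, 60),
               c(cos_term = 0.5, cos2_term = 0.25))
  set.seed(4)
  phis <- runif(50, -180, 180)
  kt <- vapply(phis, karplus_terms, numeric(2), phi0 = 60)
  expect_equal(kt[2, ], kt[1, ]^2)
})

test_that("pair distances are Euclidean, symmetric, and guard degenerate input", {
  atoms <- data.frame(resno = c(1L, 2L), elety = c("CA", "CA"),
                      resid = "GLY")
  pool <- conformer_pool(matrix(c(0, 0, 0, 3, 4, 0), 1), atoms)
  a <- list(resno = 1, elety = "CA"); b <- list(resno = 2, elety = "CA")
  expect_equal(pair_distance(pool, 1, a, b), 5)
  expect_equal(pair_distance(pool, 1, b, a), 5)
  expect_error(pair_distance(pool, 1, a, a), "differ")
  rp <- random_backbone_pool(n_conf = 3L, seed = 9L)
  d <- pair_distance(rp, 2, list(resno = 1, elety = "N"),
                     list(resno = 4, elety = "CB"))
  i <- which(rp$atoms$resno == 1 & rp$atoms$elety == "N")
  j <- which(rp$atoms$resno == 4 & rp$atoms$elety == "CB")
  expect_equal(d, sqrt(sum((rp$xyz[2, (3 * i - 2):(3 * i)] -
                              rp$xyz[2, (3 * j - 2):(3 * j)])^2)))
})

test_that("polymer scaling and Foerster efficiency follow the closed forms", {
  expect_equal(fret_distance_scaled(10, 50, 0, 0.5), 10)
  expect_equal(fret_distance_scaled(10, 50, 9, 0), 10)
  expect_equal(fret_distance_scaled(10, 50, 9, 0.5), 10 * sqrt(59 / 50))
  expect_equal(fret_distance_scaled(10, 50, 9, 0.5), 10.8628, tolerance = 1e-4)
  expect_error(fret_distance_scaled(10, 0, 9, 0.5), "n_res")

  expect_equal(fret_efficiency(52, 52), 0.5)
  expect_equal(fret_efficiency(104, 52), 1 / 65)
  expect_lt(abs(fret_efficiency(1e-3, 52) - 1), 1e-10)
  expect_error(fret_efficiency(-1, 52), "> 0")
  # composed map is monotonically decreasing in the CA-CA distance
  r <- seq(5, 120, by = 5)
  e <- fret_efficiency(fret_distance_scaled(r, 50, 9, 0.55), 52)
  expect_true(all(diff(e) < 0))
})

test_that("radius of gyration matches the centroid-deviation oracle", {
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(8)
  cloud <- matrix(rnorm(60), 20, 3)
  ctr <- colMeans(cloud)
  oracle <- sqrt(mean(rowSums(sweep(cloud, 2, ctr)^2)))
  expect_equal(radius_of_gyration(cloud), oracle)
  m <- runif(20, 1, 16)
  ctr_w <- colSums(cloud * m / sum(m))
  oracle_w <- sqrt(sum(m / sum(m) * rowSums(sweep(cloud, 2, ctr_w)^2)))
  expect_equal(radius_of_gyration(cloud, masses = m), oracle_w)
})

test_that("geometric observables are invariant under rigid-body transforms", {
  pool <- random_backbone_pool(n_conf = 3L, n_res = 5L, seed = 21L)
  moved <- pool
  for (i in seq_len(pool$n_conformers))
    moved$xyz[i, ] <- apply_rigid(pool$xyz[i, ], seed = 100L + i)
  for (i in seq_len(pool$n_conformers)) {
    for (r in 2:5)
      expect_equal(compute_phi(moved, i, r), compute_phi(pool, i, r),
                   tolerance = 1e-8)
    a <- list(resno = 1, elety = "CA"); b <- list(resno = 5, elety = "CA")
    expect_equal(pair_distance(moved, i, a, b), pair_distance(pool, i, a, b),
                 tolerance = 1e-8)
  }
  expect_equal(rg_from_pool(moved), rg_from_pool(pool), tolerance = 1e-8)
})

test_that("pool-derived tables agree with the scalar operations", {
  pool <- random_backbone_pool(n_conf = 4L, n_res = 6L, seed = 13L)
  cfg <- uncertainty_config()

  jc_rs <- restraint_set(as.character(2:5), target = 6, datatype = "JC")
  jt <- jc_table_from_pool(pool, jc_rs, phi0 = cfg$jc$phi0)
  for (i in 1:4) for (j in 1:4)
    expect_equal(jt$values[i, j],
                 unname(karplus_terms(compute_phi(pool, i, j + 1L),
                                      cfg$jc$phi0)["cos_term"]))
  expect_identical(jt$cos2, jt$values^2)

  pairs <- data.frame(id = c("d1", "d2"),
                      resno_a = c(1L, 2L), elety_a = c("H", "CB"),
                      resno_b = c(4L, 6L), elety_b = c("H", "H"))
  noe_rs <- restraint_set(pairs$id, target = NA, datatype = "NOE",
                          lo = 0, hi = 8)
  dt <- distance_table_from_pool(pool, pairs, noe_rs, "NOE")
  expect_equal(dt$values[3, 2],
               pair_distance(pool, 3, list(resno = 2, elety = "CB"),
                             list(resno = 6, elety = "H")))

  fr_rs <- restraint_set("E1", target = 0.5, datatype = "FRET")
  fpairs <- data.frame(id = "E1", resno_a = 1L, resno_b = 6L)
  ft <- fret_table_from_pool(pool, fpairs, fr_rs, cfg)
  r <- pair_distance(pool, 2, list(resno = 1, elety = "CA"),
                     list(resno = 6, elety = "CA"))
  expect_equal(ft$values[2, 1],
               fret_efficiency(fret_distance_scaled(r, 5, cfg$fret$n_linker,
                                                    cfg$fret$upsilon),
                               cfg$fret$r0))

  # heavy-atom default drops hydrogens from R_g
  rg_all <- vapply(1:4, function(i)
    radius_of_gyration(matrix(pool$xyz[i, ], ncol = 3, byrow = TRUE)),
    numeric(1))
  expect_false(isTRUE(all.equal(rg_from_pool(pool), rg_all)))
})

test_that("multi-model PDB files read into pools, model = conformer", {
  pool <- random_backbone_pool(n_conf = 3L, n_res = 3L, seed = 2L)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  con <- file(tmp, "w")
  for (m in 1:3) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (k in seq_len(nrow(pool$atoms))) {
      xyz <- pool$xyz[m, (3 * k - 2):(3 * k)]
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        k, pool$atoms$elety[k], pool$atoms$resid[k], pool$atoms$resno[k],
        xyz[1], xyz[2], xyz[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  rd <- read_pool(tmp, labels = c("A", "A", "B"))
  expect_equal(rd$n_conformers, 3L)
  expect_equal(rd$labels, c("A", "A", "B"))
  for (i in 1:3)
    expect_equal(compute_phi(rd, i, 2L), compute_phi(pool, i, 2L),
                 tolerance = 1e-3)  # PDB fixed-width rounding
})
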