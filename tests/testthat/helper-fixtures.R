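# Shared fixture builders: everything is generated in code at test time.

# a complete small synthetic study: pool + pseudo-experimental restraints +
# scoring context over the requested data types
make_study <- function(n_pool = 300L, types = NULL,
                       weights = c(A = 0.5, B = 0.5), noise = TRUE,
                       seed = 42L, spreads = NULL,
                       counts = c(CS = 40L, JC = 30L, NOE = 30L, PRE = 30L,
                                  RDC = 15L, SAXS = 37L, RH = 1L, FRET = 1L)) {
  truth <- synthetic_truth(n_pool = n_pool, counts = counts,
                           spreads = spreads)
  pool <- make_pool(truth, seed = seed)
  exper <- make_experimental(pool, weights, noise = noise, seed = seed + 1L)
  if (!is.null(types)) exper <- exper[types]
  ctx <- synthetic_context(pool, exper)
  list(truth = truth, pool = pool, exper = exper, ctx = ctx)
}

# a small all-atom-ish backbone pool with random (non-physical) coordinates:
# residues 1..n_res carrying N, CA, C, HN, CB atoms
random_backbone_pool <- function(n_conf = 4L, n_res = 5L, seed = 1L,
                                 labels = NULL) {
  set.seed(seed)
  elety <- c("N", "CA", "C", "H", "CB")
  atoms <- data.frame(resno = rep(seq_len(n_res), each = length(elety)),
                      elety = rep(elety, n_res),
                      resid = "ALA", stringsAsFactors = FALSE)
  xyz <- matrix(rnorm(n_conf * nrow(atoms) * 3L, sd = 4), nrow = n_conf)
  conformer_pool(xyz, atoms, labels = labels)
}

# random rigid-body transform applied to one conformer's flat xyz row
apply_rigid <- function(flat_xyz, seed = 1L) {
  set.seed(seed)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  shift <- rnorm(3, sd = 20)
  m <- matrix(flat_xyz, ncol = 3L, byrow = TRUE)
  as.vector(t(m %*% t(qr_rot) + matrix(shift, nrow(m), 3, byrow = TRUE)))
}

# numerical oracle for the offset model: 1-D maximization over q
offset_oracle <- function(target, ens_avg, sigma_q, sigma_ex) {
  f <- function(q) dnorm(q, 0, sigma_q, log = TRUE) +
    dnorm(target - q - ens_avg, 0, sigma_ex, log = TRUE)
  span <- 10 * (sigma_q + sigma_ex) + abs(target - ens_avg)
  opt <- optimize(f, c(-span, span), maximum = TRUE, tol = 1e-12)
  list(q = opt$maximum, logp = opt$objective)
}

# numerical oracle for the Karplus model: 3-D BFGS maximization over (A,B,C)
karplus_oracle <- function(a1, a2, target_j, kp, sigma_ex) {
  nll <- function(p) -(dnorm(p[1], kp$mu_A, kp$sigma_A, log = TRUE) +
                         dnorm(p[2], kp$mu_B, kp$sigma_B, log = TRUE) +
                         dnorm(p[3], kp$mu_C, kp$sigma_C, log = TRUE) +
                         dnorm(target_j - (p[1] * a2 + p[2] * a1 + p[3]),
                               0, sigma_ex, log = TRUE))
  grad <- function(p) {
    eps <- target_j - (p[1] * a2 + p[2] * a1 + p[3])
    c((p[1] - kp$mu_A) / kp$sigma_A^2 - eps * a2 / sigma_ex^2,
      (p[2] - kp$mu_B) / kp$sigma_B^2 - eps * a1 / sigma_ex^2,
      (p[3] - kp$mu_C) / kp$sigma_C^2 - eps / sigma_ex^2)
  }
  opt <- optim(c(kp$mu_A, kp$mu_B, kp$mu_C), nll, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
  list(par = opt$par, logp = -opt$value)
}

# write a restraint TSV from a data frame (columns as given)
write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
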