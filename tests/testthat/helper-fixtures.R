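# Shared fixtures built in code.

# two-eye clustered regression data with known compound-symmetry residuals
sim_clusters <- function(n, rho, beta = c(1, 0.5, -0.2), sigma = 1,
                         subject_level = TRUE, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  b <- rnorm(n, 0, sigma * sqrt(rho))
  e <- matrix(rnorm(2 * n, 0, sigma * sqrt(1 - rho)), n, 2)
  if (!subject_level) {
    x1 <- cbind(x1, rnorm(n)); x2 <- cbind(x2, rnorm(n))
  } else {
    x1 <- cbind(x1, x1); x2 <- cbind(x2, x2)
  }
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + b + e
  tibble::tibble(
    subject_id = rep(sprintf("S%03d", 1:n), 2),
    x1 = as.vector(x1), x2 = as.vector(x2), y = as.vector(y)
  )
}

# subject/eye tables with a prescribed number of both-eye QC failures and
# pathology exclusions
make_qc_tables <- function(n, n_both_fail, n_pathology, group = "MS",
                           prefix = "S") {
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  fail_ids <- ids[seq_len(n_both_fail)]
  path_ids <- ids[n_both_fail + seq_len(n_pathology)]
  subjects <- tibble::tibble(subject_id = ids, group = group,
                             pathology = ids %in% path_ids)
  eyes <- tibble::tibble(
    subject_id = rep(ids, each = 2),
    eye = rep(c("OD", "OS"), n),
    qc_pass = !rep(ids %in% fail_ids, each = 2)
  )
  list(subjects = subjects, eyes = eyes)
}
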