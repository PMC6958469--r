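# fixture builders and independent oracles used across the suite

# noiseless 4PL curve on a log-spaced grid centered at the ec50
make_4pl_curve <- function(top = 1, bottom = 0, hill = 1, ec50 = 10,
                           decades = 2, n = 9, agent = "agent") {
  d <- ec50 * 10^seq(-decades, decades, length.out = n)
  v <- bottom + (top - bottom) / (1 + (d / ec50)^hill)
  dose_response_curve(d, v, agent = agent)
}

# self-combination sham: both "agents" are the same drug (same 4PL, equal
# top concentrations), so a mixture at fraction f contains f * top of drug
# regardless of the weights and its response is the single-agent curve
sham_combination <- function(hill = 1, ec50 = 5, top = NULL,
                             weights = default_ratio_weights()) {
  if (is.null(top)) top <- 20 * ec50
  single <- make_4pl_curve(hill = hill, ec50 = ec50, decades = 1.4,
                           agent = "drug")
  design <- fixed_ratio_design(top, top, weights = weights)
  f_grid <- (ec50 / top) * 10^seq(-1.2, 1.2, length.out = 9)
  mixtures <- lapply(seq_len(nrow(weights)), function(i) {
    d <- f_grid * top  # wA + wB = 1, tops equal
    dose_response_curve(f_grid, 1 / (1 + (d / ec50)^hill),
                        agent = "sham mixture", unit = "fraction of top")
  })
  list(design = design, single = single, mixtures = mixtures)
}

# brute-force oracle: combined-dose fraction at which a true survival
# surface crosses the 50% level, by dense grid search plus root polishing
oracle_f50 <- function(surv_fn, n_grid = 1e4, f_lo = 1e-8, f_hi = 1e4) {
  f <- 10^seq(log10(f_lo), log10(f_hi), length.out = n_grid)
  s <- surv_fn(f)
  i <- which(diff(sign(s - 0.5)) != 0)[1]
  stopifnot(is.finite(i))
  stats::uniroot(function(x) surv_fn(x) - 0.5, c(f[i], f[i + 1]),
                 tol = 1e-12)$root
}

# oracle CI for a plate_sim_spec surface at one weight pair
oracle_ci <- function(spec, w_a, w_b) {
  f50 <- oracle_f50(function(f)
    plate_true_survival(spec, f * w_a * spec$top_conc_a,
                        f * w_b * spec$top_conc_b))
  f50 * w_a * spec$top_conc_a / spec$agent_a$ec50 +
    f50 * w_b * spec$top_conc_b / spec$agent_b$ec50
}

# exhaustive permutation p-value for a two-group mean difference
perm_p <- function(x, y) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  stats <- apply(idx, 2, function(i) abs(mean(pool[i]) - mean(pool[-i])))
  mean(stats >= obs - 1e-12)
}

withr_tempdir <- function() {
  d <- tempfile("ttcsyn")
  dir.create(d)
  d
}
withr_tempfile <- function(name) file.path(withr_tempdir(), name)

th227 <- nuclide("Th-227", 18.7, "days")
ra223 <- nuclide("Ra-223", 11.43, "days")
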