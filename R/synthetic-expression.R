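#' Specification of a synthetic nRPKM expression matrix
#'
#' Emulates the statistical structure of sorted-microglia expression
#' profiles: per-gene log2 baselines, two genotype groups, planted
#' log2-scale effects on named gene modules in the second group,
#' iid Gaussian noise on the log2 scale, and dropout zeros applied at the
#' nRPKM scale (exact zeros) so the detection/imputation rule is exercised.
#'
#' Defaults mirror a small sorted-cell study: 1000 genes, 7 samples per
#' group (the sorted-microglia comparison used 7 vs 6 animals), baseline
#' log2 mean 4 with gene-level SD 1, residual noise SD 0.5 and dropout
#' probability 0.1.
#'
#' @param n_genes number of genes; ids are `g0001`, `g0002`, ...
#' @param n_samples_per_group samples per group (groups `A` and `B`).
#' @param modules named list of gene-id vectors (subsets of the universe).
#' @param effects named numeric vector of planted log2 effects (group B
#'   minus group A), one per module.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 expression.
#' @param noise_sd residual SD on the log2 scale.
#' @param dropout probability in \[0, 1) of zeroing a value at the nRPKM
#'   scale.
#' @param seed RNG seed.
#' @return list of class `ExprSpec`.
#' @export
expr_spec <- function(n_genes = 1000, n_samples_per_group = 7,
                      modules = list(), effects = numeric(0),
                      baseline_log2_mean = 4, baseline_log2_sd = 1,
                      noise_sd = 0.5, dropout = 0.1, seed = 1L) {
  if (n_genes < 1 || n_samples_per_group < 1) stop("counts must be positive")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must lie in [0, 1)")
  if (noise_sd < 0 || baseline_log2_sd < 0) stop("SDs must be >= 0")
  universe <- sprintf("g%04d", seq_len(n_genes))
  for (nm in names(modules)) {
    bad <- setdiff(modules[[nm]], universe)
    if (length(bad))
      stop("module '", nm, "' references unknown gene(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  if (length(effects) && !all(names(effects) %in% names(modules)))
    stop("`effects` must be named after modules")
  structure(list(n_genes = n_genes,
                 n_samples_per_group = n_samples_per_group,
                 modules = modules, effects = effects,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, dropout = dropout,
                 seed = as.integer(seed), universe = universe),
            class = "ExprSpec")
}

#' Simulate an nRPKM expression matrix with planted module effects
#'
#' Values are `2^(baseline_g + effect_g * [group == B] + noise)`, with
#' dropout zeros applied independently afterwards. Deterministic per seed.
#'
#' @param spec an [expr_spec()].
#' @return list of class `ExpressionSim`: `matrix` (genes x samples, nRPKM
#'   scale, with dimnames), `groups` (named vector sample -> `"A"`/`"B"`),
#'   and `truth` (planted per-module effects and module memberships).
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "ExprSpec"))
  set.seed(spec$seed)
  n <- spec$n_samples_per_group
  samples <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  groups <- stats::setNames(rep(c("A", "B"), each = n), samples)

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_log2_mean,
                           spec$baseline_log2_sd)
  effect_g <- numeric(spec$n_genes)
  names(effect_g) <- spec$universe
  for (nm in names(spec$modules)) {
    eff <- if (nm %in% names(spec$effects)) spec$effects[[nm]] else 0
    effect_g[spec$modules[[nm]]] <- effect_g[spec$modules[[nm]]] + eff
  }
  lmat <- matrix(baseline, spec$n_genes, 2 * n) +
    outer(effect_g, as.numeric(groups == "B")) +
    matrix(stats::rnorm(spec$n_genes * 2 * n, 0, spec$noise_sd),
           spec$n_genes, 2 * n)
  m <- 2^lmat
  if (spec$dropout > 0) {
    drop <- matrix(stats::runif(length(m)) < spec$dropout,
                   nrow(m), ncol(m))
    m[drop] <- 0
  }
  dimnames(m) <- list(spec$universe, samples)
  structure(list(matrix = m, groups = groups,
                 truth = list(effects = spec$effects,
                              modules = spec$modules)),
            class = "ExpressionSim")
}
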