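#' Floored log2 transform of an expression matrix
#'
#' `max(log2(x), floor)` elementwise: the transform applied to nRPKM-scale
#' values before z-scoring for heat-map display. Zeros (undetected genes)
#' map to the floor.
#'
#' @param m numeric genes x samples matrix of nRPKM-scale values (>= 0).
#' @param floor lower bound on the log2 scale, default -4.
#' @return matrix of floored log2 values.
#' @export
log2_floor <- function(m, floor = -4) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  out <- suppressWarnings(log2(m))
  out[out < floor | !is.finite(out)] <- floor
  out
}

#' Per-gene z-scores of a log2 expression matrix
#'
#' Each gene (row) is centered and scaled so a value is the distance, in
#' SDs, of a sample's expression from that gene's mean across all samples
#' in the dataset. The SD uses the n-1 denominator. Zero-variance rows are
#' set to all zeros.
#'
#' @param lm numeric genes x samples matrix (log2 scale).
#' @return matrix of the same shape.
#' @export
zscore_by_gene <- function(lm) {
  lm <- as.matrix(lm)
  if (ncol(lm) < 2L) stop("z-scoring requires at least two samples")
  mu <- rowMeans(lm)
  sd <- apply(lm, 1, stats::sd)
  z <- (lm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Gene set score per sample
#'
#' A sample's gene set score is the average difference, over all genes in
#' the set, between that sample's log2(nRPKM) value and the gene's mean
#' log2(nRPKM) across all samples. When a gene is undetected (nRPKM = 0) in
#' one or more samples, those samples receive an imputed log2 value one
#' log2 step below the lowest detected log2(nRPKM) for that gene in the
#' sample set. Genes undetected in every sample are dropped from the set.
#' By construction the scores of one set sum to zero across samples.
#'
#' @param m numeric genes x samples matrix of nRPKM-scale values with
#'   rownames (gene ids) and colnames (sample ids).
#' @param genes character vector of gene ids in the set (genes absent from
#'   the matrix are dropped with a warning).
#' @param set_name name recorded in the output.
#' @param floor optional log2 floor applied after imputation (`NULL`, the
#'   default, leaves values unfloored; the floor belongs to the heat-map
#'   display transform).
#' @return data frame of class `GeneSetScoreTable`: one row per sample with
#'   `sample`, `gene_set`, `score`, `n_genes`, `n_imputed`.
#' @examples
#' m <- matrix(c(0, 4, 8), 1, 3,
#'             dimnames = list("g1", c("s1", "s2", "s3")))
#' gene_set_score(m, "g1")$score  # -1, 0, 1
#' @export
gene_set_score <- function(m, genes, set_name = "set", floor = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have gene rownames and sample colnames")
  if (any(m < 0)) stop("expression values must be non-negative")
  present <- genes[genes %in% rownames(m)]
  if (length(present) == 0L)
    stop("gene set '", set_name, "' has no genes present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " gene(s) of set '", set_name,
            "' absent from the matrix; dropped")
  sub <- m[present, , drop = FALSE]
  detected_any <- rowSums(sub > 0) > 0
  if (!all(detected_any)) {
    message(sum(!detected_any), " gene(s) undetected in all samples dropped from '",
            set_name, "'")
    sub <- sub[detected_any, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("gene set '", set_name, "' has no detected genes")
  }
  lm <- suppressWarnings(log2(sub))
  n_imp <- integer(ncol(sub))
  for (i in seq_len(nrow(sub))) {
    zero <- sub[i, ] == 0
    if (any(zero)) {
      lm[i, zero] <- min(lm[i, !zero]) - 1  # one log2 step below lowest detected
      n_imp <- n_imp + as.integer(zero)
    }
  }
  if (!is.null(floor)) lm[lm < floor] <- floor
  dev <- lm - rowMeans(lm)
  out <- data.frame(sample = colnames(sub), gene_set = set_name,
                    score = colMeans(dev), n_genes = nrow(sub),
                    n_imputed = n_imp, row.names = NULL)
  class(out) <- c("GeneSetScoreTable", "data.frame")
  out
}

#' Score several gene sets at once
#'
#' @param m genes x samples nRPKM matrix.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param floor optional log2 floor, see [gene_set_score()].
#' @return row-bound `GeneSetScoreTable` over all sets.
#' @export
gene_set_scores <- function(m, sets, floor = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- do.call(rbind, lapply(names(sets), function(nm)
    gene_set_score(m, sets[[nm]], set_name = nm, floor = floor)))
  class(out) <- c("GeneSetScoreTable", "data.frame")
  out
}

#' Welch comparison of gene set scores between groups
#'
#' Two-tailed t test assuming unequal variance between groups
#' (Welch-Satterthwaite degrees of freedom). Two identical groups return
#' `t = 0, p = 1`.
#'
#' @param a,b numeric score vectors for the two groups (>= 2 values each).
#' @return list with `t`, `df`, `p`, `mean_diff` (mean(b) - mean(a)).
#' @export
compare_scores <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two samples")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, mean_diff = 0))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0,
                mean_diff = mean(b) - mean(a)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(b) - mean(a))
}

#' Compare every gene set's scores between two groups
#'
#' @param scores a `GeneSetScoreTable` (from [gene_set_scores()]).
#' @param groups named character/factor vector mapping sample id to group;
#'   must contain exactly two groups.
#' @param adjust apply Benjamini-Hochberg correction across sets (off by
#'   default; per-set tests are reported as-is).
#' @return data frame: `gene_set`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `mean_diff`, `t`, `df`, `p` (and `p_adj` when requested).
#' @export
compare_score_table <- function(scores, groups, adjust = FALSE) {
  stopifnot(inherits(scores, "data.frame"))
  glev <- sort(unique(as.character(groups)))
  if (length(glev) != 2L) stop("exactly two groups are required")
  res <- lapply(split(scores, scores$gene_set), function(d) {
    g <- as.character(groups[d$sample])
    if (anyNA(g)) stop("sample(s) missing from the group map")
    a <- d$score[g == glev[1]]; b <- d$score[g == glev[2]]
    w <- compare_scores(a, b)
    data.frame(gene_set = d$gene_set[1], group_a = glev[1], group_b = glev[2],
               mean_a = mean(a), mean_b = mean(b), mean_diff = w$mean_diff,
               t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
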