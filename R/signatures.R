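#' Filter an expression matrix by minimum expression
#'
#' Retains genes whose log2 expression exceeds `min_expression` in at
#' least `min_fraction_samples` of samples. The sample set is unchanged.
#'
#' @param mat numeric matrix, genes x samples, rownames = gene ids.
#' @param min_expression log2-scale expression threshold (default 1).
#' @param min_fraction_samples fraction of samples that must exceed it
#'   (default 0.2).
#' @return the filtered matrix.
#' @export
filter_genes <- function(mat, min_expression = 1, min_fraction_samples = 0.2) {
  stopifnot(is.matrix(mat), min_expression >= 0, min_fraction_samples >= 0)
  keep <- rowMeans(mat > min_expression) >= min_fraction_samples
  if (!any(keep)) stop("no genes pass the expression filter")
  mat[keep, , drop = FALSE]
}

#' Gene-wise Z-scores across samples
#'
#' Per gene: (value - gene mean) / gene SD, with the sample (n-1) SD.
#' Zero-variance genes get an all-zero row and are recorded in the
#' `zero_variance` attribute.
#'
#' @param mat numeric matrix, genes x samples, >= 2 samples.
#' @return Z matrix of the same shape, attribute `zero_variance` holding
#'   the ids of flat genes.
#' @export
zscore_genes <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("Z-scoring needs >= 2 samples")
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  flat <- sdv == 0
  sdv[flat] <- 1  # placeholder; rows zeroed below
  z <- (mat - mu) / sdv
  z[flat, ] <- 0
  attr(z, "zero_variance") <- rownames(mat)[flat]
  z
}

#' Mean-Z signature score
#'
#' The per-sample lineage score: mean of gene-wise Z-scored expression
#' over the marker genes of one epithelial subset. Markers absent from
#' the matrix are dropped (never imputed); the number used is recorded.
#'
#' @param z Z matrix from [zscore_genes()].
#' @param gene_set character vector of marker gene ids.
#' @param name subset name used in error messages.
#' @return list with `score` (named per-sample vector) and `n_genes_used`.
#' @export
signature_score_meanz <- function(z, gene_set, name = "gene set") {
  stopifnot(is.matrix(z), length(gene_set) > 0)
  present <- intersect(unique(gene_set), rownames(z))
  if (length(present) == 0L) {
    stop(sprintf("no marker of '%s' is present in the matrix", name))
  }
  sub <- z[present, , drop = FALSE]
  list(score = colMeans(sub), n_genes_used = length(present))
}

#' Rank-based signature score
#'
#' A labelled rank-based stand-in for single-sample enrichment scoring:
#' within each sample, genes are mid-ranked by expression; the score is
#' the mean marker rank centred and rescaled to [-1, 1]
#' (score = (mean rank - (G+1)/2) / ((G-1)/2) for G genes). Invariant
#' under any within-sample monotone transform of expression. The maximum
#' attainable score for a set of size k is (G-k)/(G-1).
#'
#' @param mat expression matrix (not Z-scored), genes x samples.
#' @param gene_set character vector of marker gene ids.
#' @param name subset name used in error messages.
#' @return list with `score` and `n_genes_used` as in
#'   [signature_score_meanz()].
#' @export
signature_score_rank <- function(mat, gene_set, name = "gene set") {
  stopifnot(is.matrix(mat), length(gene_set) > 0)
  present <- intersect(unique(gene_set), rownames(mat))
  if (length(present) == 0L) {
    stop(sprintf("no marker of '%s' is present in the matrix", name))
  }
  G <- nrow(mat)
  ranks <- apply(mat, 2L, rank)
  mean_rank <- colMeans(ranks[present, , drop = FALSE])
  list(score = (mean_rank - (G + 1) / 2) / ((G - 1) / 2),
       n_genes_used = length(present))
}

#' Score a collection of marker gene sets
#'
#' Applies the chosen scorer to every subset and returns a long table.
#'
#' @param mat expression matrix, genes x samples.
#' @param gene_sets named list of marker gene id vectors.
#' @param scorer `"meanz"` (Z-scores computed internally) or `"rank"`.
#' @return data.frame with columns `sample`, `subset`, `score`,
#'   `n_genes_used`.
#' @export
score_signatures <- function(mat, gene_sets, scorer = c("meanz", "rank")) {
  scorer <- match.arg(scorer)
  stopifnot(is.list(gene_sets), length(gene_sets) > 0,
            !is.null(names(gene_sets)))
  base <- if (scorer == "meanz") zscore_genes(mat) else mat
  fun <- if (scorer == "meanz") signature_score_meanz else signature_score_rank
  rows <- lapply(names(gene_sets), function(nm) {
    sc <- fun(base, gene_sets[[nm]], name = nm)
    data.frame(sample = names(sc$score), subset = nm,
               score = unname(sc$score), n_genes_used = sc$n_genes_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-mean signature scores
#'
#' Arithmetic mean score per (treatment, subset), the quantity shown in
#' group-mean heatmaps.
#'
#' @param scores long table from [score_signatures()].
#' @param samples data.frame with columns `sample` and `treatment`
#'   labelling every scored sample.
#' @return data.frame with columns `subset`, `treatment`, `mean_score`,
#'   ordered subsets x treatments.
#' @export
group_mean_scores <- function(scores, samples) {
  stopifnot(all(c("sample", "subset", "score") %in% names(scores)),
            all(c("sample", "treatment") %in% names(samples)))
  idx <- match(scores$sample, samples$sample)
  if (anyNA(idx)) {
    stop(sprintf("unlabelled sample(s): %s",
                 paste(unique(scores$sample[is.na(idx)]), collapse = ", ")))
  }
  scores$treatment <- samples$treatment[idx]
  agg <- stats::aggregate(score ~ subset + treatment, data = scores, FUN = mean)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg[order(agg$subset, agg$treatment), , drop = FALSE]
}

#' Read marker gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path GMT file path.
#' @return named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write marker gene sets to a GMT file
#'
#' @param gene_sets named list of gene id vectors.
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
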