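#' Convert counts to transcripts per million (TPM)
#'
#' TPM for gene g in sample i is the length-normalized count rate scaled
#' to a library of one million:
#' `TPM_gi = (count_gi / length_g) / sum_g'(count_g'i / length_g') * 1e6`.
#' Every TPM column sums to 1e6 (up to floating-point error).
#'
#' @param counts A tibble with first column `gene` and one numeric column
#'   per sample (raw counts), e.g. `cohort$counts` from
#'   [generate_counts()].
#' @param lengths A tibble with columns `gene` and `length` (nt), or a
#'   named numeric vector.
#' @return A tibble of the same shape holding TPM values.
#' @examples
#' counts <- tibble::tibble(gene = c("a", "b"), s1 = c(10, 20))
#' counts_to_tpm(counts, tibble::tibble(gene = c("a", "b"),
#'                                      length = c(1000, 2000)))
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as_tibble(counts)
  if (names(counts)[1] != "gene") abort("first column must be `gene`")
  if (is.numeric(lengths) && !is.null(names(lengths))) {
    lengths <- tibble(gene = names(lengths), length = unname(lengths))
  }
  len <- lengths$length[match(counts$gene, lengths$gene)]
  if (anyNA(len)) {
    abort(sprintf("missing length for gene(s): %s",
                  paste(head(counts$gene[is.na(len)], 5), collapse = ", ")))
  }
  out <- counts
  for (s in names(counts)[-1]) {
    rate <- counts[[s]] / len
    denom <- sum(rate)
    if (denom <= 0) abort(sprintf("sample %s has zero library size", s))
    out[[s]] <- rate / denom * 1e6
  }
  out
}

#' Per-gene log2 fold change between group means
#'
#' Computes `log2((mean_lesion + pc) / (mean_control + pc))` per gene
#' from a TPM table, where the groups come from the sample sheet. The
#' pseudocount guards against zero means.
#'
#' @param tpm A tibble (first column `gene`, one column per sample) of
#'   TPM values.
#' @param samples Sample sheet tibble with columns `sample` and `group`
#'   (exactly two groups).
#' @param pseudocount Positive pseudocount added to both means (default 1
#'   TPM).
#' @param case,control Group labels; default `"lesion"` vs `"control"`.
#' @return A tibble: `gene`, `log2fc`.
#' @export
log2_fold_change <- function(tpm, samples, pseudocount = 1,
                             case = "lesion", control = "control") {
  stopifnot(pseudocount > 0)
  grp <- split(samples$sample, samples$group)
  if (!all(c(case, control) %in% names(grp))) {
    abort(sprintf("sample sheet must contain groups '%s' and '%s'",
                  case, control))
  }
  m_case <- rowMeans(as.matrix(tpm[, grp[[case]], drop = FALSE]))
  m_ctrl <- rowMeans(as.matrix(tpm[, grp[[control]], drop = FALSE]))
  tibble(gene = tpm$gene,
         log2fc = log2((m_case + pseudocount) / (m_ctrl + pseudocount)))
}

#' Per-pair log2 fold-change profiles
#'
#' For a paired design, computes one log2 ratio per patient pair and gene:
#' `log2((TPM_lesion + pc) / (TPM_control + pc))`. The resulting gene x
#' pair profile matrix is the natural input to [consensus_cluster()].
#'
#' @inheritParams log2_fold_change
#' @return A tibble: `gene`, one column per patient.
#' @export
log2fc_profiles <- function(tpm, samples, pseudocount = 1,
                            case = "lesion", control = "control") {
  stopifnot(pseudocount > 0)
  if (!"patient" %in% names(samples)) {
    abort("sample sheet must have a `patient` column for paired profiles")
  }
  out <- tibble(gene = tpm$gene)
  for (p in unique(samples$patient)) {
    s_case <- samples$sample[samples$patient == p & samples$group == case]
    s_ctrl <- samples$sample[samples$patient == p & samples$group == control]
    if (length(s_case) != 1 || length(s_ctrl) != 1) {
      abort(sprintf("patient %s does not have exactly one sample per group", p))
    }
    out[[p]] <- log2((tpm[[s_case]] + pseudocount) /
                     (tpm[[s_ctrl]] + pseudocount))
  }
  out
}

#' Rank-based per-gene differential expression test
#'
#' Two-sided Wilcoxon rank-sum test per gene between the two groups
#' (exact when both groups have at most 10 samples and the gene has no
#' ties, mid-rank normal approximation otherwise, matching
#' [stats::wilcox.test()]). A gene constant across all samples gets
#' p = 1.
#'
#' @inheritParams log2_fold_change
#' @return A tibble: `gene`, `p`.
#' @export
rank_de_test <- function(tpm, samples, case = "lesion", control = "control") {
  grp <- split(samples$sample, samples$group)
  if (!all(c(case, control) %in% names(grp))) {
    abort(sprintf("sample sheet must contain groups '%s' and '%s'",
                  case, control))
  }
  a <- as.matrix(tpm[, grp[[case]], drop = FALSE])
  b <- as.matrix(tpm[, grp[[control]], drop = FALSE])
  if (ncol(a) < 2 || ncol(b) < 2) abort("need >= 2 samples per group")
  p <- vapply(seq_len(nrow(tpm)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (max(c(x, y)) == min(c(x, y))) return(1)
    suppressWarnings(wilcox.test(x, y, exact = length(x) <= 10 &&
                                   length(y) <= 10)$p.value)
  }, 0)
  tibble(gene = tpm$gene, p = pmin(p, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving on input
#' indices and clipped to \[0, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` are
#'   rejected.
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p)) abort("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression table
#'
#' Composes [counts_to_tpm()] (when given counts), [log2_fold_change()],
#' [rank_de_test()] and [bh_fdr()] into the per-gene differential
#' expression table, with the significance filter
#' `fdr < fdr_alpha & |log2fc| > lfc_min` (strict inequalities).
#'
#' @param tpm A TPM tibble (first column `gene`).
#' @param samples Sample sheet tibble (`sample`, `group`).
#' @param fdr_alpha FDR threshold (default 0.05, strict `<`).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.01,
#'   strict `>`).
#' @param pseudocount Pseudocount for the fold change.
#' @return A tibble: `gene`, `log2fc`, `p`, `fdr`, `passes_filter`.
#' @export
de_table <- function(tpm, samples, fdr_alpha = 0.05, lfc_min = 0.01,
                     pseudocount = 1) {
  lfc <- log2_fold_change(tpm, samples, pseudocount = pseudocount)
  pv <- rank_de_test(tpm, samples)
  out <- dplyr::left_join(lfc, pv, by = "gene")
  out$fdr <- bh_fdr(out$p)
  out$passes_filter <- out$fdr < fdr_alpha & abs(out$log2fc) > lfc_min
  out
}

#' Apply the differential-expression significance filter
#'
#' Keeps genes with `fdr < fdr_alpha` and `|log2fc| > lfc_min`, both
#' strict, and returns their ids.
#'
#' @param det A DE table with columns `gene`, `log2fc`, `fdr` (e.g. from
#'   [de_table()]).
#' @param fdr_alpha,lfc_min Thresholds (strict inequalities).
#' @return Character vector of gene ids passing the filter.
#' @export
de_filter <- function(det, fdr_alpha = 0.05, lfc_min = 0.01) {
  det$gene[det$fdr < fdr_alpha & abs(det$log2fc) > lfc_min]
}
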