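AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Per-column conservation by Jensen-Shannon divergence
#'
#' Scores each alignment column by the Jensen-Shannon divergence between the
#' column's empirical amino-acid distribution `p` and a background
#' distribution `q`: with mixture `m = (p + q) / 2`, the divergence is
#' `KL(p || m) / 2 + KL(q || m) / 2`, normalised to `[0, 1]` by dividing by
#' `log 2`. A fully conserved column diverges maximally from a diffuse
#' background and scores near 1; a column matching the background scores 0.
#'
#' Gaps are excluded from `p` and reported separately as `gap_fraction`; an
#' all-gap column gets an `NA` score and is flagged. With `window > 0` the
#' focal score is combined with the mean score of up to `window` flanking
#' columns on each side at weight `1 - mix_weight` (windowing off by
#' default).
#'
#' @param aln Alignment tibble (`id`, `seq`) from [read_alignment()], or a
#'   named character vector of equal-length gapped sequences.
#' @param columns Columns to score (default: all).
#' @param background `"uniform"` (default) or a named numeric vector over the
#'   20 amino acids summing to 1.
#' @param mix_weight Weight of the focal column when window smoothing is on;
#'   in `[0, 1]`, default 0.5.
#' @param window Number of flanking columns on each side to average into the
#'   score; 0 (default) disables smoothing.
#' @return A tibble with columns `column`, `score`, `gap_fraction`.
#' @export
jsd_conservation <- function(aln, columns = NULL, background = "uniform",
                             mix_weight = 0.5, window = 0) {
  if (is.character(aln) && is.null(dim(aln)) && !is.null(names(aln))) {
    aln <- tibble::tibble(id = names(aln), seq = unname(aln))
  }
  stopifnot(mix_weight >= 0, mix_weight <= 1, window >= 0)
  mat <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  L <- ncol(mat)
  if (is.null(columns)) columns <- seq_len(L)
  stopifnot(all(columns >= 1), all(columns <= L))

  if (identical(background, "uniform")) {
    q <- stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    q <- background[AA20]
    if (anyNA(q) || abs(sum(q) - 1) > 1e-6) {
      stop("background must be a distribution over the 20 amino acids")
    }
  }

  kl <- function(p, m) {
    nz <- p > 0
    sum(p[nz] * log(p[nz] / m[nz]))
  }
  score_one <- function(j) {
    ch <- mat[, j]
    gapf <- mean(ch %in% c("-", "."))
    obs <- ch[ch %in% AA20]
    if (length(obs) == 0) return(c(NA_real_, gapf))
    p <- stats::setNames(tabulate(match(obs, AA20), 20) / length(obs), AA20)
    m <- (p + q) / 2
    c((kl(p, m) + kl(q, m)) / 2 / log(2), gapf)
  }

  # raw scores over the whole alignment so windows have flanking context
  raw <- vapply(seq_len(L), score_one, numeric(2))
  scores <- raw[1, ]
  if (window > 0) {
    sm <- scores
    for (j in seq_len(L)) {
      flank <- setdiff(max(1, j - window):min(L, j + window), j)
      fl <- scores[flank]
      fl <- fl[!is.na(fl)]
      if (length(fl) > 0 && !is.na(scores[j])) {
        sm[j] <- mix_weight * scores[j] + (1 - mix_weight) * mean(fl)
      }
    }
    scores <- sm
  }
  tibble::tibble(column = as.integer(columns), score = scores[columns],
                 gap_fraction = raw[2, columns])
}
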