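ARG_CODONS <- c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
PHENOTYPES <- c("HCM", "DCM", "RCM", "LVNC", "other")

#' Gene model: a coding sequence and its translation
#'
#' Validates the reading frame, trims a trailing stop codon, rejects
#' internal stops, and stores the translated protein.
#'
#' @param gene Gene symbol (e.g. `"TNNT2"`).
#' @param cds Coding DNA (or RNA; U is converted to T).
#' @return An object of class `gene_model`: list with `gene`, `cds`
#'   (stop-trimmed), `codons`, `protein`.
#' @export
gene_model <- function(gene, cds) {
  cds <- toupper(gsub("U", "T", gsub("\\s", "", cds)))
  if (nchar(cds) %% 3 != 0) stop("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- codon_table()
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("invalid codon in CDS")
  if (length(aa) > 0 && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) stop("internal stop codon at codon ", which(aa == "*")[1])
  structure(list(gene = gene, cds = paste(codons, collapse = ""),
                 codons = codons, protein = paste(aa, collapse = "")),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene, "-", length(x$codons), "codons\n")
  invisible(x)
}

#' Census of arginine codons in a coding sequence
#'
#' Arginine is encoded by six codons (CGT/CGU, CGC, CGA, CGG, AGA, AGG);
#' four of them carry a CpG dinucleotide, which makes arginine codons
#' mutation-prone. This tallies each arginine codon type across the CDS
#' reading frame; the counts sum to the number of arginines in the protein.
#'
#' @param gm A [gene_model()].
#' @return A tibble with columns `codon`, `count` (all six arginine codons,
#'   zero counts included).
#' @export
arginine_codon_census <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  tibble::tibble(
    codon = ARG_CODONS,
    count = vapply(ARG_CODONS, function(cd) sum(gm$codons == cd), integer(1),
                   USE.NAMES = FALSE)
  )
}

#' CpG dinucleotide annotation per codon
#'
#' A codon is CpG-containing when "CG" occurs within it (offsets 1-2 or
#' 2-3). With `include_junctions`, a codon ending in C followed by a codon
#' starting with G flags both codons as junction-CpG, reported in a separate
#' column and never merged into the in-codon flag.
#'
#' @param gm A [gene_model()].
#' @param include_junctions Also flag CpGs spanning codon boundaries.
#' @return A tibble with columns `codon_index`, `codon`, `aa`,
#'   `cpg_in_codon`, `cpg_offset` (1 or 2, NA when absent) and, when
#'   requested, `junction_cpg`.
#' @export
find_cpg_codons <- function(gm, include_junctions = FALSE) {
  stopifnot(inherits(gm, "gene_model"))
  cods <- gm$codons
  off <- ifelse(substr(cods, 1, 2) == "CG", 1L,
                ifelse(substr(cods, 2, 3) == "CG", 2L, NA_integer_))
  out <- tibble::tibble(
    codon_index = seq_along(cods), codon = cods,
    aa = strsplit(gm$protein, "")[[1]],
    cpg_in_codon = !is.na(off), cpg_offset = off
  )
  if (include_junctions) {
    n <- length(cods)
    junc_after <- substr(cods, 3, 3) == "C" &
      c(substr(cods[-1], 1, 1) == "G", FALSE)
    out$junction_cpg <- junc_after | c(FALSE, junc_after[-n])
  }
  out
}

#' Parse protein substitution notation
#'
#' Accepts three-letter HGVS-style (`"p.Arg92Gln"`) and one-letter
#' (`"R92Q"`) substitution notation. Stop-gain, frameshift and other
#' non-substitution notations are rejected: the analyses cover amino-acid
#' substitutions only.
#'
#' @param x Character vector of variant strings.
#' @return A tibble with columns `ref_aa`, `position`, `alt_aa`.
#' @export
parse_variant <- function(x) {
  one <- function(v) {
    v0 <- trimws(v)
    if (grepl("fs|del|dup|ins|Ter|\\*", v0)) {
      stop("not an amino-acid substitution: ", v0)
    }
    m3 <- regmatches(v0, regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", v0))[[1]]
    if (length(m3) == 4) {
      aa <- suppressWarnings(bio3d::aa321(toupper(m3[c(2, 4)])))
      if (anyNA(aa) || any(aa == "X")) stop("unknown amino-acid code in: ", v0)
      return(c(aa[1], m3[3], aa[2]))
    }
    m1 <- regmatches(v0, regexec("^([A-Z])([0-9]+)([A-Z])$", v0))[[1]]
    if (length(m1) == 4) {
      if (!all(m1[c(2, 4)] %in% AA20)) stop("unknown amino-acid code in: ", v0)
      return(m1[2:4])
    }
    stop("unparseable variant notation: ", v0)
  }
  m <- vapply(x, one, character(3), USE.NAMES = FALSE)
  tibble::tibble(ref_aa = m[1, ], position = as.integer(m[2, ]),
                 alt_aa = m[3, ])
}

#' Read a curated variant/case table
#'
#' Reads a delimited case table with the documented header: `case_id`,
#' `gene`, `variant`, `index_flag`, `phenotype`, optional `sex`,
#' `last_followup_age`, event flags `cv_death`, `scd`, `hf_death_tx`,
#' `stroke_death`, `proc_death`, and `n_path_variants`. The variant column
#' is parsed into `ref_aa` / `position` / `alt_aa`. Cause-specific flags
#' that contradict `cv_death`, or multiple cause flags on one case, raise a
#' warning.
#'
#' @param path CSV/TSV file path.
#' @return A case tibble.
#' @export
read_cases <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  cases <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  req <- c("case_id", "gene", "variant", "index_flag", "phenotype",
           "last_followup_age", "cv_death", "scd", "hf_death_tx",
           "stroke_death", "proc_death", "n_path_variants")
  missing <- setdiff(req, names(cases))
  if (length(missing) > 0) {
    stop("case table missing columns: ", paste(missing, collapse = ", "))
  }
  cases <- cases[setdiff(names(cases), c("ref_aa", "position", "alt_aa"))]
  cases <- dplyr::bind_cols(cases, parse_variant(cases$variant))
  validate_cases(cases)
  cases
}

validate_cases <- function(cases) {
  flags <- c("scd", "hf_death_tx", "stroke_death", "proc_death")
  cause_n <- rowSums(cases[flags] == 1)
  if (any(cause_n > 1)) {
    warning(sum(cause_n > 1), " case(s) with more than one cause-specific death flag")
  }
  if (any(cause_n >= 1 & cases$cv_death != 1)) {
    warning("cause-specific death flag set without cv_death")
  }
  invisible(cases)
}

#' Per-site summary of variant cases
#'
#' Tallies cases per (gene, position): index-case count, phenotype
#' breakdown, and (when a gene model is supplied) the reference codon with
#' its arginine and CpG flags. When the table carries a `classification`
#' column, disputed records are excluded and only pathogenic / likely
#' pathogenic records are counted.
#'
#' @param cases Case tibble (see [read_cases()]), with `gene`, `position`,
#'   `ref_aa`, `index_flag`, `phenotype` columns.
#' @param gm Optional [gene_model()] for the gene being summarised.
#' @param index_only Count only index cases (default TRUE), mirroring how
#'   variant frequencies are reported per proband.
#' @return A tibble with one row per variant site: `gene`, `position`,
#'   `ref_aa`, `n_index_cases`, one count column per phenotype, and codon
#'   annotation columns when `gm` is given.
#' @export
variant_site_summary <- function(cases, gm = NULL, index_only = TRUE) {
  if ("classification" %in% names(cases)) {
    cases <- cases[cases$classification %in% c("pathogenic", "likely_pathogenic"), ]
  }
  if (index_only) cases <- cases[cases$index_flag == 1, ]
  if (!is.null(gm)) {
    plen <- nchar(gm$protein)
    over <- cases$gene == gm$gene & cases$position > plen
    if (any(over)) {
      warning(sum(over), " case(s) at positions beyond the protein length skipped")
      cases <- cases[!over, ]
    }
  }
  cases$phenotype <- ifelse(cases$phenotype %in% PHENOTYPES,
                            cases$phenotype, "other")
  out <- cases |>
    dplyr::count(.data$gene, .data$position, .data$ref_aa, .data$phenotype) |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "n",
                       values_fill = 0L)
  for (ph in PHENOTYPES) if (!ph %in% names(out)) out[[ph]] <- 0L
  out <- out |>
    dplyr::mutate(n_index_cases = rowSums(dplyr::pick(dplyr::all_of(PHENOTYPES)))) |>
    dplyr::select("gene", "position", "ref_aa", "n_index_cases",
                  dplyr::all_of(PHENOTYPES)) |>
    dplyr::arrange(.data$gene, .data$position)
  if (!is.null(gm)) {
    cpg <- find_cpg_codons(gm)
    idx <- match(out$position, cpg$codon_index)
    out$codon <- cpg$codon[idx]
    out$is_cpg_codon <- cpg$cpg_in_codon[idx]
    out$is_arg <- out$ref_aa == "R"
  }
  out
}

#' Call recurrent-variant hotspots
#'
#' A site is a hotspot when its index-case count reaches the threshold. The
#' threshold is a tunable definition (default 5 index cases), since
#' recurrence has no universal cutoff.
#'
#' @param summaries Output of [variant_site_summary()].
#' @param threshold Minimum index-case count (default 5).
#' @return Hotspot rows sorted by count (descending) then position, with a
#'   `threshold` column recording the rule used.
#' @export
call_hotspots <- function(summaries, threshold = 5) {
  stopifnot(threshold >= 1)
  summaries |>
    dplyr::filter(.data$n_index_cases >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$n_index_cases), .data$position) |>
    dplyr::mutate(threshold = threshold)
}

#' Chi-square test of association on a contingency table
#'
#' Pearson chi-square without continuity correction (the convention of the
#' clinical statistics software the analyses mirror), with the fraction of
#' cells with expected count below 5 reported so small-table results can be
#' flagged. Zero-margin rows/columns are dropped with a warning. A Fisher
#' exact test is available for small tables.
#'
#' @param tab A matrix/table of counts, or a data frame of counts with row
#'   categories in the first column.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `frac_expected_lt5` (NA for Fisher).
#' @export
association_chi2 <- function(tab, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (is.data.frame(tab)) {
    tab <- as.matrix(tibble::column_to_rownames(tab, names(tab)[1]))
  }
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero-margin rows/columns dropped")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p_value = ft$p.value, frac_expected_lt5 = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p_value = ct$p.value,
                 frac_expected_lt5 = mean(ct$expected < 5))
}
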