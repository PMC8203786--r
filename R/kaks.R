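NUC <- c("A", "C", "G", "T")

codon_table <- function() Biostrings::GENETIC_CODE

#' All 61 sense codons of the standard genetic code
#' @return Character vector of DNA codons.
#' @export
sense_codons <- function() {
  gc <- codon_table()
  names(gc)[gc != "*"]
}

translate_codons <- function(codons) {
  gc <- codon_table()
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("invalid codon: ", paste(codons[is.na(aa)], collapse = ", "))
  aa
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts potential synonymous (`S`) and nonsynonymous (`N`) sites of a
#' sense codon in the counting-method convention: for each of the nine
#' possible single-nucleotide changes, the fraction of changes at that
#' position that are synonymous accumulates into `S`, the rest into `N`, so
#' `S + N = 3` exactly. Changes creating a stop codon count as
#' nonsynonymous.
#'
#' @param codon A DNA codon string (e.g. `"CGG"`); vectorised.
#' @return A tibble with columns `codon`, `S`, `N`.
#' @export
syn_nonsyn_sites <- function(codon) {
  gc <- codon_table()
  one <- function(cd) {
    cd <- toupper(cd)
    aa <- gc[cd]
    if (is.na(aa)) stop("invalid codon: ", cd)
    if (aa == "*") stop("stop codon has no site counts: ", cd)
    s <- 0
    nts <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(NUC, nts[pos])) {
        mut <- nts
        mut[pos] <- alt
        maa <- gc[paste(mut, collapse = "")]
        if (maa != "*" && maa == aa) s <- s + 1 / 3
      }
    }
    s
  }
  S <- vapply(codon, one, numeric(1))
  tibble::tibble(codon = toupper(codon), S = unname(S), N = 3 - unname(S))
}

# permutations of 1..n for n <= 3
perms123 <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous/nonsynonymous differences between two codons
#'
#' Counts observed synonymous and nonsynonymous differences on minimal
#' mutational paths between two sense codons. When the codons differ at more
#' than one position, all orderings of the single-nucleotide steps are
#' enumerated and averaged with equal weights; paths passing through a stop
#' codon are excluded. If every path passes through a stop, all paths are
#' averaged with steps into or out of a stop counted as nonsynonymous.
#'
#' @param ref,alt Sense codon strings.
#' @return Named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
codon_path_counts <- function(ref, alt) {
  gc <- codon_table()
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.na(gc[ref]) || gc[ref] == "*") stop("invalid reference codon: ", ref)
  if (is.na(gc[alt]) || gc[alt] == "*") stop("invalid alternate codon: ", alt)
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  diffs <- which(r != a)
  nd <- length(diffs)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))

  walk <- function(order) {
    cur <- r
    syn <- 0; nonsyn <- 0; hits_stop <- FALSE
    for (pos in diffs[order]) {
      prev_aa <- gc[paste(cur, collapse = "")]
      cur[pos] <- a[pos]
      new_aa <- gc[paste(cur, collapse = "")]
      if (prev_aa == "*" || new_aa == "*") {
        hits_stop <- TRUE
        nonsyn <- nonsyn + 1
      } else if (new_aa == prev_aa) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
    }
    c(syn = syn, nonsyn = nonsyn, stop = as.numeric(hits_stop))
  }
  paths <- vapply(perms123[[nd]], walk, numeric(3))
  ok <- paths["stop", ] == 0
  use <- if (any(ok)) paths[, ok, drop = FALSE] else paths
  c(syn = mean(use["syn", ]), nonsyn = mean(use["nonsyn", ]))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Threads each coding sequence through its gapped protein sequence so that
#' every amino-acid column becomes one codon column; a protein gap becomes a
#' `---` triple. A trailing stop codon on a CDS is trimmed. The translation
#' of each CDS must reproduce the ungapped protein sequence exactly.
#'
#' @param protein_aln Alignment tibble (`id`, `seq`) or named character
#'   vector of gapped amino-acid sequences.
#' @param cds Named character vector (or tibble `id`, `seq`) of unaligned
#'   coding DNA sequences, one per aligned id.
#' @param reference_id Optional id of the reference (human) sequence, stored
#'   as an attribute and used by [site_kaks()].
#' @return A tibble with columns `id`, `codons` (gapped codon string), class
#'   `codon_alignment`, with attribute `reference_id`.
#' @export
back_translate <- function(protein_aln, cds, reference_id = NULL) {
  if (is.character(protein_aln)) {
    protein_aln <- tibble::tibble(id = names(protein_aln),
                                  seq = unname(protein_aln))
  }
  if (is.data.frame(cds)) cds <- stats::setNames(cds$seq, cds$id)
  cds <- toupper(gsub("U", "T", cds))
  gc <- codon_table()
  stops <- names(gc)[gc == "*"]

  rows <- vapply(seq_len(nrow(protein_aln)), function(i) {
    id <- protein_aln$id[i]
    gapped <- strsplit(toupper(protein_aln$seq[i]), "")[[1]]
    prot <- gapped[gapped != "-"]
    if (!id %in% names(cds) || is.na(cds[[id]])) {
      stop("no CDS supplied for id: ", id)
    }
    s <- cds[[id]]
    if (nchar(s) %% 3 != 0) stop("CDS length not a multiple of 3 for id: ", id)
    codons <- if (nchar(s) == 0) character(0) else {
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    }
    if (length(codons) > 0 && codons[length(codons)] %in% stops) {
      codons <- codons[-length(codons)]
    }
    if (length(codons) != length(prot)) {
      stop("CDS length mismatch for id ", id, ": ", length(codons),
           " codons vs ", length(prot), " residues")
    }
    aa <- unname(gc[codons])
    if (anyNA(aa)) stop("invalid codon in CDS for id: ", id)
    if (any(aa == "*")) {
      stop("internal stop codon in CDS for id ", id, " at codon ",
           which(aa == "*")[1])
    }
    bad <- which(aa != prot)
    if (length(bad) > 0) {
      col <- which(cumsum(gapped != "-") == bad[1] & gapped != "-")[1]
      stop("translation mismatch for id ", id, " at alignment column ", col)
    }
    out <- character(length(gapped))
    out[gapped == "-"] <- "---"
    out[gapped != "-"] <- codons
    paste(out, collapse = "")
  }, character(1))

  out <- tibble::tibble(id = protein_aln$id, codons = rows)
  attr(out, "reference_id") <- reference_id %||% protein_aln$id[1]
  class(out) <- c("codon_alignment", class(out))
  out
}

codon_at <- function(codon_aln, column) {
  substr(codon_aln$codons, 3 * (column - 1) + 1, 3 * column)
}

#' Site-specific Ka/Ks from a codon alignment
#'
#' A counting estimator of per-column selective pressure: each non-reference
#' sequence ungapped at the column is compared with the reference codon;
#' synonymous and nonsynonymous differences are counted on minimal
#' mutational paths ([codon_path_counts()]), and per-pair site counts are
#' the mean of the two codons' potential sites ([syn_nonsyn_sites()]).
#' Pooled proportions `pS = Sd / sum(S_sites)` and `pN = Nd / sum(N_sites)`
#' are Jukes-Cantor corrected (`K = -3/4 log(1 - 4p/3)`); a proportion at or
#' above 0.75 cannot be corrected and is used raw with a `saturated` flag.
#' `omega = Ka / Ks`; when no substitutions are observed omega is undefined
#' (`NA`); when `Ks = 0` with `Ka > 0`, omega is set to `omega_max` and
#' flagged capped rather than infinite.
#'
#' Selection classes: `negative` for `omega < 1 - neutral_tol`, `neutral`
#' within the tolerance band around 1, `positive` above it, `undefined` when
#' omega is `NA`. Columns where the reference is gapped, or with fewer than
#' `min_seqs` ungapped sequences, are returned undefined.
#'
#' @param codon_aln A `codon_alignment` from [back_translate()].
#' @param columns Codon columns to estimate (default: all).
#' @param reference_id Reference sequence id (default: the alignment's
#'   `reference_id` attribute).
#' @param omega_max Cap for omega (default 10).
#' @param min_seqs Minimum ungapped sequences per column (default 4).
#' @param neutral_tol Half-width of the neutral band around omega = 1
#'   (default 0.05).
#' @return A tibble with one row per column: `column`, `ref_codon`,
#'   `ref_aa`, `n_seqs`, `Sd`, `Nd`, `S_sites`, `N_sites`, `Ka`, `Ks`,
#'   `omega`, `selection_class`, `saturated`, `capped`.
#' @export
site_kaks <- function(codon_aln, columns = NULL, reference_id = NULL,
                      omega_max = 10, min_seqs = 4, neutral_tol = 0.05) {
  reference_id <- reference_id %||% attr(codon_aln, "reference_id")
  ri <- which(codon_aln$id == reference_id)
  if (length(ri) != 1) stop("reference id not found once in alignment: ",
                            reference_id)
  L <- nchar(codon_aln$codons[1]) / 3
  if (is.null(columns)) columns <- seq_len(L)
  gc <- codon_table()

  undefined_row <- function(col, ref_codon = NA_character_, n_seqs = NA_integer_) {
    tibble::tibble(column = col, ref_codon = ref_codon,
                   ref_aa = if (is.na(ref_codon)) NA_character_ else unname(gc[ref_codon]),
                   n_seqs = n_seqs, Sd = NA_real_, Nd = NA_real_,
                   S_sites = NA_real_, N_sites = NA_real_, Ka = NA_real_,
                   Ks = NA_real_, omega = NA_real_,
                   selection_class = "undefined", saturated = FALSE,
                   capped = FALSE)
  }

  jc <- function(p) {
    if (p < 0.75) list(k = -0.75 * log(1 - 4 * p / 3), sat = FALSE)
    else list(k = p, sat = TRUE)
  }

  purrr::map_dfr(columns, function(col) {
    cods <- codon_at(codon_aln, col)
    ref <- cods[ri]
    if (ref == "---") return(undefined_row(col))
    others <- cods[-ri]
    others <- others[others != "---"]
    n_seqs <- length(others) + 1L
    if (n_seqs < min_seqs) return(undefined_row(col, ref, n_seqs))

    ref_sites <- syn_nonsyn_sites(ref)
    Sd <- 0; Nd <- 0; Ss <- 0; Ns <- 0
    for (oc in others) {
      d <- codon_path_counts(ref, oc)
      Sd <- Sd + d[["syn"]]
      Nd <- Nd + d[["nonsyn"]]
      os <- syn_nonsyn_sites(oc)
      Ss <- Ss + (ref_sites$S + os$S) / 2
      Ns <- Ns + (ref_sites$N + os$N) / 2
    }

    if (Sd == 0 && Nd == 0) {
      out <- undefined_row(col, ref, n_seqs)
      out$Sd <- 0; out$Nd <- 0; out$S_sites <- Ss; out$N_sites <- Ns
      out$Ka <- 0; out$Ks <- 0
      return(out)
    }
    ks_c <- jc(Sd / Ss)
    ka_c <- jc(Nd / Ns)
    Ka <- ka_c$k; Ks <- ks_c$k
    capped <- FALSE
    if (Ks == 0) {
      omega <- omega_max; capped <- TRUE
    } else {
      omega <- Ka / Ks
      if (omega > omega_max) { omega <- omega_max; capped <- TRUE }
    }
    cls <- if (omega < 1 - neutral_tol) "negative"
           else if (omega <= 1 + neutral_tol) "neutral" else "positive"
    tibble::tibble(column = col, ref_codon = ref, ref_aa = unname(gc[ref]),
                   n_seqs = n_seqs, Sd = Sd, Nd = Nd, S_sites = Ss,
                   N_sites = Ns, Ka = Ka, Ks = Ks, omega = omega,
                   selection_class = cls, saturated = ka_c$sat || ks_c$sat,
                   capped = capped)
  })
}

#' Combined per-site conservation and selection table
#'
#' Composes [jsd_conservation()], [back_translate()] and [site_kaks()] into
#' a per-column table joined on alignment column, with the reference
#' sequence's ungapped position added.
#'
#' @inheritParams back_translate
#' @inheritParams site_kaks
#' @param ... Passed to [jsd_conservation()] (background, window, ...).
#' @return A tibble with columns `column`, `ref_position`, `ref_aa`,
#'   `conservation`, `gap_fraction`, `Ka`, `Ks`, `omega`, `selection_class`.
#' @export
site_selection_table <- function(protein_aln, cds, reference_id = NULL,
                                 omega_max = 10, min_seqs = 4,
                                 neutral_tol = 0.05, ...) {
  if (is.character(protein_aln)) {
    protein_aln <- tibble::tibble(id = names(protein_aln),
                                  seq = unname(protein_aln))
  }
  reference_id <- reference_id %||% protein_aln$id[1]
  cons <- jsd_conservation(protein_aln, ...)
  caln <- back_translate(protein_aln, cds, reference_id)
  kaks <- site_kaks(caln, reference_id = reference_id, omega_max = omega_max,
                    min_seqs = min_seqs, neutral_tol = neutral_tol)
  refg <- strsplit(protein_aln$seq[protein_aln$id == reference_id], "")[[1]]
  refpos <- ifelse(refg != "-", cumsum(refg != "-"), NA_integer_)
  kaks |>
    dplyr::left_join(dplyr::rename(cons, conservation = "score"),
                     by = "column") |>
    dplyr::mutate(ref_position = as.integer(refpos[.data$column])) |>
    dplyr::select("column", "ref_position", "ref_aa", "conservation",
                  "gap_fraction", "Ka", "Ks", "omega", "selection_class",
                  "Sd", "Nd", "n_seqs", "saturated", "capped")
}
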