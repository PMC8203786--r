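#' Synthetic two-chain-plus complexes with planted contacts
#'
#' Builds a toy multi-chain complex in PDB format with one (glycine-like)
#' CA atom per residue. Chains are laid out on parallel, widely separated
#' lines so that no inter-chain atom pair is near the contact cutoff; each
#' planted contact then moves the second residue's atom to exactly the
#' requested distance from the first. The planted pairs are therefore the
#' complete ground-truth contact set at any cutoff at or above the largest
#' planted distance (and below the decoy chain separation).
#'
#' Geometry constraints checked up front (an unrealisable spec errors):
#' planted distances must be below `chain_sep`; a moved residue may be
#' planted only once; and the anchor residues of two planted contacts may
#' not sit within two positions of each other on the same chain, which
#' keeps moved atoms from fabricating contacts between themselves.
#'
#' @param n_chains Number of chains (labelled A, B, ...).
#' @param n_residues Residues per chain (recycled across chains).
#' @param planted Data frame with columns `chain_a`, `pos_a`, `chain_b`,
#'   `pos_b`, `distance`; `NULL` for no contacts.
#' @param chain_sep Baseline separation between chain lines (Angstrom,
#'   default 30).
#' @param jitter Decoy geometry scale: uniform z-noise added to unmoved
#'   atoms (default 0.5).
#' @param seed Integer seed; output is byte-identical for equal spec + seed.
#' @return A list with `pdb` (character vector of PDB lines), `truth`
#'   (tibble `chain_a`, `pos_a`, `chain_b`, `pos_b`, `distance`), and
#'   `coords` (tibble of the atom layout).
#' @export
make_complex <- function(n_chains = 3, n_residues = 30, planted = NULL,
                         chain_sep = 30, jitter = 0.5, seed = 1) {
  stopifnot(n_chains >= 2, all(n_residues >= 2), chain_sep > 10)
  n_residues <- rep_len(n_residues, n_chains)
  chains <- LETTERS[seq_len(n_chains)]
  res_sep <- 3.8

  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("chain_a", "pos_a", "chain_b", "pos_b", "distance") %in%
                    names(planted)))
    if (any(planted$distance >= chain_sep / 2)) {
      stop("unrealisable spec: planted distance too close to chain separation")
    }
    if (any(planted$chain_a == planted$chain_b)) {
      stop("unrealisable spec: planted contact within one chain")
    }
    bkey <- paste(planted$chain_b, planted$pos_b)
    if (anyDuplicated(bkey) || any(bkey %in% paste(planted$chain_a, planted$pos_a))) {
      stop("unrealisable spec: a residue is moved by more than one contact")
    }
    for (ch in unique(planted$chain_a)) {
      pa <- sort(planted$pos_a[planted$chain_a == ch])
      if (length(pa) > 1 && any(diff(pa) < 3)) {
        stop("unrealisable spec: anchor residues closer than 3 positions on chain ", ch)
      }
    }
  }

  set.seed(seed)
  coords <- purrr::map_dfr(seq_len(n_chains), function(k) {
    tibble::tibble(chain = chains[k], resno = seq_len(n_residues[k]),
                   x = seq_len(n_residues[k]) * res_sep,
                   y = k * chain_sep,
                   z = stats::runif(n_residues[k], -jitter, jitter))
  })

  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      a <- which(coords$chain == planted$chain_a[i] &
                   coords$resno == planted$pos_a[i])
      b <- which(coords$chain == planted$chain_b[i] &
                   coords$resno == planted$pos_b[i])
      if (length(a) != 1 || length(b) != 1) {
        stop("unrealisable spec: planted residue not present")
      }
      dir_y <- if (coords$y[b] >= coords$y[a]) 1 else -1
      coords$x[b] <- coords$x[a]
      coords$y[b] <- coords$y[a] + dir_y * planted$distance[i]
      coords$z[b] <- coords$z[a]
    }
  }

  pdb <- character(nrow(coords) + 1)
  for (i in seq_len(nrow(coords))) {
    pdb[i] <- sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, coords$chain[i], coords$resno[i],
      coords$x[i], coords$y[i], coords$z[i], 1, 0
    )
  }
  pdb[length(pdb)] <- "END"

  truth <- if (is.null(planted) || nrow(planted) == 0) {
    tibble::tibble(chain_a = character(), pos_a = integer(),
                   chain_b = character(), pos_b = integer(),
                   distance = double())
  } else {
    swap <- planted$chain_b < planted$chain_a
    out <- planted
    out[swap, c("chain_a", "pos_a", "chain_b", "pos_b")] <-
      planted[swap, c("chain_b", "pos_b", "chain_a", "pos_a")]
    dplyr::arrange(out, .data$chain_a, .data$pos_a, .data$chain_b, .data$pos_b)
  }
  list(pdb = pdb, truth = truth, coords = coords)
}

#' Random planted-contact complex specification
#'
#' Draws a valid random planted-contact set for [make_complex()]: anchor
#' positions at least three apart per chain, each moved residue used once,
#' distances uniform in `dist_range`.
#'
#' @param n_chains,n_residues As in [make_complex()].
#' @param n_contacts Number of planted contacts.
#' @param dist_range Planted distance range (default 2.5 to 4).
#' @param seed Integer seed.
#' @return A planted-contact tibble.
#' @export
random_complex_spec <- function(n_chains = 3, n_residues = 30, n_contacts = 4,
                                dist_range = c(2.5, 4), seed = 1) {
  set.seed(seed)
  chains <- LETTERS[seq_len(n_chains)]
  out <- NULL
  used_b <- character(0)
  used_a <- list()
  anchor_keys <- character(0)
  tries <- 0
  while (is.null(out) || nrow(out) < n_contacts) {
    tries <- tries + 1
    if (tries > 500) break
    pr <- sample(chains, 2)
    pa <- sample(n_residues, 1)
    pb <- sample(n_residues, 1)
    akey <- pr[1]
    prev_a <- used_a[[akey]] %||% integer(0)
    if (any(abs(prev_a - pa) < 3)) next
    bkey <- paste(pr[2], pb)
    if (bkey %in% used_b || bkey %in% anchor_keys ||
        paste(pr[1], pa) %in% used_b) next
    used_b <- c(used_b, bkey)
    used_a[[akey]] <- c(prev_a, pa)
    anchor_keys <- c(anchor_keys, paste(pr[1], pa))
    row <- tibble::tibble(chain_a = pr[1], pos_a = pa, chain_b = pr[2],
                          pos_b = pb,
                          distance = stats::runif(1, dist_range[1], dist_range[2]))
    out <- dplyr::bind_rows(out, row)
  }
  out
}

#' Simulate ortholog coding sequences under site-specific selection
#'
#' Evolves a root coding sequence along a star phylogeny: each taxon
#' descends independently from the root (the reference "human" sequence,
#' emitted unchanged as the first record). Per codon site, mutation
#' attempts arrive as a Poisson process (`3 * branch_length` expected
#' attempts per codon per branch); each attempt draws a position and an
#' alternative nucleotide (transitions weighted by `kappa`), redrawing any
#' change that would create a stop codon. Synonymous changes are always
#' accepted; nonsynonymous changes are accepted with probability equal to
#' the site's true omega, which is how purifying selection scales the
#' nonsynonymous rate.
#'
#' @param n_taxa Number of taxa including the reference (default 26).
#' @param n_codons Codons per sequence (default 120).
#' @param omega_true True per-site omega, recycled to `n_codons`.
#' @param branch_length Expected mutation attempts per nucleotide site per
#'   branch (default 0.3).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @param reference_id Id of the root/reference record (default "human").
#' @return A list with `protein_aln` (tibble `id`, `seq`; equal-length
#'   ungapped sequences), `cds` (named character vector), and `truth`
#'   (tibble `column`, `omega_true`).
#' @export
simulate_orthologs <- function(n_taxa = 26, n_codons = 120, omega_true = 0.2,
                               branch_length = 0.3, kappa = 2, seed = 1,
                               reference_id = "human") {
  stopifnot(n_taxa >= 2, n_codons >= 1, all(omega_true >= 0),
            branch_length >= 0)
  omega_true <- rep_len(omega_true, n_codons)
  set.seed(seed)
  gc <- codon_table()
  sense <- sense_codons()
  transitions <- c(A = "G", G = "A", C = "T", T = "C")

  root <- sample(sense, n_codons, replace = TRUE)
  ids <- c(reference_id, paste0("taxon", seq_len(n_taxa - 1)))

  mutate_codon <- function(codon, omega) {
    n_events <- stats::rpois(1, 3 * branch_length)
    if (n_events == 0) return(codon)
    for (e in seq_len(n_events)) {
      for (try in 1:50) {
        pos <- sample.int(3, 1)
        nts <- strsplit(codon, "")[[1]]
        alts <- setdiff(NUC, nts[pos])
        wts <- ifelse(alts == transitions[nts[pos]], kappa, 1)
        alt <- sample(alts, 1, prob = wts)
        cand <- nts
        cand[pos] <- alt
        cand <- paste(cand, collapse = "")
        if (gc[cand] != "*") break
        cand <- NULL
      }
      if (is.null(cand)) next
      if (gc[cand] == gc[codon] || stats::runif(1) < omega) codon <- cand
    }
    codon
  }

  cds <- stats::setNames(vector("character", n_taxa), ids)
  cds[1] <- paste(root, collapse = "")
  for (t in 2:n_taxa) {
    evolved <- vapply(seq_len(n_codons),
                      function(j) mutate_codon(root[j], omega_true[j]),
                      character(1))
    cds[t] <- paste(evolved, collapse = "")
  }

  protein_aln <- tibble::tibble(
    id = ids,
    seq = vapply(cds, function(s) {
      paste(translate_codons(substring(s, seq(1, nchar(s), 3),
                                       seq(3, nchar(s), 3))), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
  list(protein_aln = protein_aln, cds = cds,
       truth = tibble::tibble(column = seq_len(n_codons),
                              omega_true = omega_true))
}

default_phenotype_probs <- function() {
  # region-wise phenotype mixes emulating the published cohort composition
  list(
    `1-89`    = c(HCM = 0.815, DCM = 0.10, RCM = 0.035, LVNC = 0.025, other = 0.025),
    `90-129`  = c(HCM = 0.92, DCM = 0.04, RCM = 0.02, LVNC = 0.01, other = 0.01),
    `130-179` = c(HCM = 0.40, DCM = 0.506, RCM = 0.044, LVNC = 0.03, other = 0.02),
    `200-288` = c(HCM = 0.90, DCM = 0.05, RCM = 0.02, LVNC = 0.02, other = 0.01)
  )
}

#' Simulate a clinical variant-carrier cohort
#'
#' Emulates the structure of a curated literature cohort: each case carries
#' one amino-acid substitution at a position drawn by region, a phenotype
#' drawn from a region-dependent mix, and cause-specific death times drawn
#' from exponential distributions whose rates can be multiplied per region
#' (hazard ratio 1 everywhere by default, i.e. a null cohort). The earliest
#' cause-specific death competes against uniform right-censoring; exactly
#' one cause flag is set for a death, and the ground truth (region, latent
#' death time, cause) is returned alongside the emitted table.
#'
#' @param n_cases Number of cases (default 300).
#' @param gene Gene symbol (default "TNNT2").
#' @param scheme Region scheme positions are drawn from (default
#'   [tnt_regions()]).
#' @param region_weights Named sampling weights over region labels.
#' @param phenotype_probs Named list (per region) of probabilities over
#'   HCM/DCM/RCM/LVNC/other.
#' @param hazards Baseline exponential rates per year for each
#'   cause-specific endpoint.
#' @param region_multipliers Named per-region hazard multipliers applied to
#'   every cause (default all 1).
#' @param censor_range Uniform censoring-age window in years (default
#'   c(30, 80)).
#' @param index_fraction Probability a case is an index case (default 0.6).
#' @param complex_fraction Fraction of cases planted with a second
#'   pathogenic variant (default 0.05); these are the cases
#'   [filter_cases()] must exclude.
#' @param arg_fraction Probability the substituted residue is an arginine
#'   (default 0.686, the arginine share among published TnT index cases).
#' @param seed Integer seed.
#' @return A list with `cases` (tibble in the documented case-table schema,
#'   plus parsed `ref_aa`/`position`/`alt_aa`) and `truth` (tibble with the
#'   planted region, latent death time, cause and censoring indicator).
#' @export
simulate_cohort <- function(n_cases = 300, gene = "TNNT2",
                            scheme = tnt_regions(),
                            region_weights = c(`1-89` = 0.15, `90-129` = 0.35,
                                               `130-179` = 0.30, `200-288` = 0.20),
                            phenotype_probs = default_phenotype_probs(),
                            hazards = c(scd = 0.004, hf_death_tx = 0.003,
                                        stroke_death = 0.0005,
                                        proc_death = 0.0005),
                            region_multipliers = NULL,
                            censor_range = c(30, 80), index_fraction = 0.6,
                            complex_fraction = 0.05, arg_fraction = 0.686,
                            seed = 1) {
  stopifnot(abs(sum(region_weights) - 1) < 1e-8, all(hazards > 0))
  regions <- scheme[scheme$type == "region", , drop = FALSE]
  labels <- names(region_weights)
  stopifnot(all(labels %in% regions$label))
  if (is.null(region_multipliers)) {
    region_multipliers <- stats::setNames(rep(1, length(labels)), labels)
  }
  set.seed(seed)

  region <- sample(labels, n_cases, replace = TRUE, prob = region_weights)
  position <- vapply(region, function(rg) {
    i <- match(rg, regions$label)
    as.integer(sample(seq(regions$start[i], regions$end[i]), 1))
  }, integer(1), USE.NAMES = FALSE)
  # one reference residue per position: recurrent cases share their site's
  # wild-type amino acid, as a real curated table would
  upos <- unique(position)
  ref_by_pos <- stats::setNames(
    ifelse(stats::runif(length(upos)) < arg_fraction, "R",
           sample(setdiff(AA20, "R"), length(upos), replace = TRUE)),
    upos
  )
  ref_aa <- unname(ref_by_pos[as.character(position)])
  alt_aa <- vapply(ref_aa, function(a) sample(setdiff(AA20, a), 1),
                   character(1), USE.NAMES = FALSE)
  phenotype <- vapply(region, function(rg) {
    p <- phenotype_probs[[rg]]
    sample(names(p), 1, prob = p)
  }, character(1), USE.NAMES = FALSE)

  mult <- unname(region_multipliers[region])
  causes <- names(hazards)
  event_times <- sapply(causes, function(cz) {
    stats::rexp(n_cases, rate = hazards[[cz]] * mult)
  })
  death_time <- apply(event_times, 1, min)
  cause <- causes[apply(event_times, 1, which.min)]
  censor_time <- stats::runif(n_cases, censor_range[1], censor_range[2])
  died <- death_time <= censor_time
  followup <- ifelse(died, death_time, censor_time)

  flags <- matrix(0L, n_cases, length(causes),
                  dimnames = list(NULL, causes))
  for (cz in causes) flags[died & cause == cz, cz] <- 1L

  cases <- tibble::tibble(
    case_id = sprintf("case%04d", seq_len(n_cases)),
    gene = gene,
    variant = paste0(ref_aa, position, alt_aa),
    index_flag = as.integer(stats::runif(n_cases) < index_fraction),
    phenotype = phenotype,
    last_followup_age = round(followup, 2),
    cv_death = as.integer(died),
    scd = flags[, "scd"],
    hf_death_tx = flags[, "hf_death_tx"],
    stroke_death = flags[, "stroke_death"],
    proc_death = flags[, "proc_death"],
    n_path_variants = ifelse(stats::runif(n_cases) < complex_fraction, 2L, 1L),
    ref_aa = ref_aa, position = position, alt_aa = alt_aa
  )
  truth <- tibble::tibble(
    case_id = cases$case_id, region = region, death_time = death_time,
    cause = cause, censored = !died, censor_time = censor_time
  )
  list(cases = cases, truth = truth)
}

#' Write a simulated cohort to CSV
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory; writes `cases.csv` and `truth.csv`.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$cases, file.path(dir, "cases.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
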