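#' Read a macromolecular structure from PDB-format text
#'
#' Parses standard PDB coordinate records (ATOM/HETATM/MODEL/ENDMDL/TER) into
#' a `structure_model`: a tidy atom table plus a chain-to-entity assignment.
#' Only the first model of a multi-model entry is retained; for alternate
#' locations the highest-occupancy record is kept (ties broken by altloc label
#' order); waters are discarded; other hetero groups (including calcium ions)
#' are retained and flagged as ligands.
#'
#' Chain-to-entity assignment is supplied, not inferred: chain labels differ
#' between crystallographic entries of the same complex, so the caller states
#' which chain is TnC, TnI, TnT, actin or tropomyosin.
#'
#' @param x Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param chain_map Named character vector mapping chain identifiers to
#'   entity names, e.g. `c(A = "TnC", B = "TnI", C = "TnT")`. Chains not
#'   named are labelled `"unassigned"`. All names must be chains present in
#'   the file.
#' @param entry_id Optional identifier stored with the model (e.g. `"1J1E"`).
#'
#' @return An object of class `structure_model`: a list with elements
#'   `entry_id`, `atoms` (a tibble with columns `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `elesy`, `x`, `y`, `z`, `o`, `alt`, `is_ligand`),
#'   `chain_to_entity` and `model_index`.
#' @export
read_structure <- function(x, chain_map = NULL, entry_id = NA_character_) {
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    if (is.na(entry_id)) entry_id <- sub("\\.pdb$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }

  # first model only
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1) > 0) lines <- lines[seq_len(end1[1] - 1)]

  is_coord <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(is_coord)) stop("no ATOM records found: empty model")
  for (i in which(is_coord)) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54)
    )))
    if (anyNA(coords) || any(!is.finite(coords))) {
      stop("malformed coordinate line at line ", i, ": ", trimws(lines[i]))
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- tibble::as_tibble(pdb$atom)

  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found: empty model")

  # altloc resolution: highest occupancy, ties by altloc label order
  at$o[is.na(at$o)] <- 1
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid,
                    .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  atoms <- tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), insert = at$insert,
    resid = at$resid, elety = at$elety, elesy = toupper(at$elesy),
    x = at$x, y = at$y, z = at$z, o = at$o, alt = at$alt,
    is_ligand = at$type == "HETATM"
  ) |>
    dplyr::arrange(.data$chain, .data$resno)

  chains <- unique(atoms$chain)
  if (!is.null(chain_map)) {
    bad <- setdiff(names(chain_map), chains)
    if (length(bad) > 0) {
      stop("chain_map names not present in structure: ",
           paste(bad, collapse = ", "))
    }
  }
  c2e <- stats::setNames(rep("unassigned", length(chains)), chains)
  if (!is.null(chain_map)) c2e[names(chain_map)] <- unname(chain_map)

  structure(
    list(entry_id = entry_id, atoms = atoms, chain_to_entity = c2e,
         model_index = 1L),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$entry_id, "\n")
  cat("  atoms:", nrow(x$atoms), " chains:",
      paste0(names(x$chain_to_entity), " (", x$chain_to_entity, ")",
             collapse = ", "), "\n")
  invisible(x)
}

# map 3-letter residue names to 1-letter codes, "X" for non-standard
aa3_to_1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !(out %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))] <- "X"
  out
}

contact_cols <- function() {
  tibble::tibble(
    entity_a = character(), chain_a = character(), pos_a = integer(),
    aa_a = character(), entity_b = character(), chain_b = character(),
    pos_b = integer(), aa_b = character(), min_distance = double()
  )
}

#' Inter-chain residue contacts at a distance cutoff
#'
#' A residue pair on different chains is in contact when the minimum Euclidean
#' distance over all non-hydrogen atom pairs is less than or equal to
#' `cutoff` (inclusive at the boundary). Hydrogens, if present, are ignored:
#' the crystallographic structures the method targets lack them, and
#' including them in models that have them would make cutoffs incomparable.
#' Ligand atoms (HETATM) never participate; calcium-ion proximities are
#' reported separately by [calcium_binding_residues()].
#'
#' @param model A `structure_model` from [read_structure()].
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#'
#' @return A tibble of contacts with columns `entity_a`, `chain_a`, `pos_a`,
#'   `aa_a`, `entity_b`, `chain_b`, `pos_b`, `aa_b`, `min_distance`.
#'   Positions are author residue numbers; use [build_residue_map()] and
#'   [renumber_contacts()] to convert to canonical human numbering. Each pair
#'   is reported once, with endpoints ordered by `(chain, resno)`.
#' @export
interchain_contacts <- function(model, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  at <- model$atoms[!model$atoms$is_ligand &
                      !(model$atoms$elesy %in% c("H", "D")), , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) < 2) {
    warning("model has fewer than two polymer chains; no inter-chain contacts")
    return(contact_cols())
  }

  res <- list()
  pairs <- utils::combn(sort(chains), 2, simplify = FALSE)
  for (pr in pairs) {
    a <- at[at$chain == pr[1], , drop = FALSE]
    b <- at[at$chain == pr[2], , drop = FALSE]
    A <- cbind(a$x, a$y, a$z)
    B <- cbind(b$x, b$y, b$z)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    res[[length(res) + 1]] <- tibble::tibble(
      chain_a = pr[1], pos_a = a$resno[hit[, 1]], resid_a = a$resid[hit[, 1]],
      chain_b = pr[2], pos_b = b$resno[hit[, 2]], resid_b = b$resid[hit[, 2]],
      d = sqrt(d2[hit])
    )
  }
  if (length(res) == 0) return(contact_cols())

  c2e <- model$chain_to_entity
  dplyr::bind_rows(res) |>
    dplyr::group_by(.data$chain_a, .data$pos_a, .data$resid_a,
                    .data$chain_b, .data$pos_b, .data$resid_b) |>
    dplyr::summarise(min_distance = min(.data$d), .groups = "drop") |>
    dplyr::transmute(
      entity_a = unname(c2e[.data$chain_a]), chain_a = .data$chain_a,
      pos_a = as.integer(.data$pos_a), aa_a = aa3_to_1(.data$resid_a),
      entity_b = unname(c2e[.data$chain_b]), chain_b = .data$chain_b,
      pos_b = as.integer(.data$pos_b), aa_b = aa3_to_1(.data$resid_b),
      min_distance = .data$min_distance
    ) |>
    dplyr::arrange(.data$chain_a, .data$pos_a, .data$chain_b, .data$pos_b)
}

#' Residues in contact with bound calcium ions
#'
#' The calcium-binding annotation: protein residues with any non-hydrogen
#' atom within `cutoff` of a Ca2+ ion (HETATM residue name "CA"). The source
#' structures do not define calcium-binding residues operationally, so the
#' same distance rule as the contact search is applied.
#'
#' @inheritParams interchain_contacts
#' @return A tibble with columns `entity`, `chain`, `pos`, `aa`,
#'   `min_distance`.
#' @export
calcium_binding_residues <- function(model, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  ca <- model$atoms[model$atoms$is_ligand & model$atoms$resid == "CA" &
                      model$atoms$elesy == "CA", , drop = FALSE]
  prot <- model$atoms[!model$atoms$is_ligand &
                        !(model$atoms$elesy %in% c("H", "D")), , drop = FALSE]
  empty <- tibble::tibble(entity = character(), chain = character(),
                          pos = integer(), aa = character(),
                          min_distance = double())
  if (nrow(ca) == 0 || nrow(prot) == 0) return(empty)
  P <- cbind(prot$x, prot$y, prot$z)
  Q <- cbind(ca$x, ca$y, ca$z)
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * (P %*% t(Q))
  d2[d2 < 0] <- 0
  dmin <- sqrt(apply(d2, 1, min))
  keep <- dmin <= cutoff + 1e-12
  if (!any(keep)) return(empty)
  c2e <- model$chain_to_entity
  tibble::tibble(chain = prot$chain[keep], pos = prot$resno[keep],
                 resid = prot$resid[keep], d = dmin[keep]) |>
    dplyr::group_by(.data$chain, .data$pos, .data$resid) |>
    dplyr::summarise(min_distance = min(.data$d), .groups = "drop") |>
    dplyr::transmute(entity = unname(c2e[.data$chain]), chain = .data$chain,
                     pos = as.integer(.data$pos), aa = aa3_to_1(.data$resid),
                     min_distance = .data$min_distance) |>
    dplyr::arrange(.data$chain, .data$pos)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal format into a tidy two-column tibble.
#'
#' @param path File path.
#' @param format `"auto"` (sniff a CLUSTAL header), `"fasta"` or `"clustal"`.
#' @return A tibble with columns `id` and `seq` (gapped, `-` for gaps).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "clustal") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(aln)
  } else {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  seqs <- gsub("\\.", "-", toupper(seqs))
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences are not aligned: unequal gapped lengths")
  }
  tibble::tibble(id = names(seqs), seq = unname(seqs))
}

#' Map residue positions between two aligned sequences
#'
#' Pairs ungapped positions of two sequences column by column in a multiple
#' sequence alignment: a column gapped in either sequence produces no pair,
#' so the map is injective and never maps to a sentinel. This is how author
#' residue numbering of a homologous structure is translated to canonical
#' human numbering.
#'
#' @param alignment A tibble with columns `id`, `seq` (see
#'   [read_alignment()]), or a named character vector of gapped sequences.
#' @param source_id,target_id Sequence identifiers; each must occur exactly
#'   once in the alignment.
#' @return A tibble with columns `source_pos`, `target_pos` (both 1-based in
#'   the respective ungapped sequences), with attributes `source_id` and
#'   `target_id`.
#' @export
build_residue_map <- function(alignment, source_id, target_id) {
  if (is.character(alignment)) {
    alignment <- tibble::tibble(id = names(alignment), seq = unname(alignment))
  }
  get_seq <- function(id) {
    hit <- which(alignment$id == id)
    if (length(hit) == 0) stop("identifier not found in alignment: ", id)
    if (length(hit) > 1) stop("duplicate identifier in alignment: ", id)
    alignment$seq[hit]
  }
  s <- strsplit(get_seq(source_id), "")[[1]]
  t <- strsplit(get_seq(target_id), "")[[1]]
  if (length(s) != length(t)) stop("aligned sequences have unequal length")
  if (length(s) == 0) stop("empty sequence")
  s_un <- s != "-"
  t_un <- t != "-"
  keep <- s_un & t_un
  out <- tibble::tibble(source_pos = cumsum(s_un)[keep],
                        target_pos = cumsum(t_un)[keep])
  attr(out, "source_id") <- source_id
  attr(out, "target_id") <- target_id
  out
}

#' Renumber contact positions through residue maps
#'
#' Applies per-entity residue maps (typically structure author numbering to
#' canonical human numbering) to a contact table. Contacts with either
#' endpoint unmapped are dropped, with the dropped count reported as a
#' message.
#'
#' @param contacts A contact tibble from [interchain_contacts()].
#' @param maps A named list of residue maps from [build_residue_map()], keyed
#'   by entity name. Entities without a map are left unchanged.
#' @return The contact tibble with `pos_a`/`pos_b` renumbered.
#' @export
renumber_contacts <- function(contacts, maps) {
  lookup <- function(entity, pos) {
    if (is.null(maps[[entity]])) return(pos)
    m <- maps[[entity]]
    i <- match(pos, m$source_pos)
    ifelse(is.na(i), NA_integer_, m$target_pos[i])
  }
  out <- contacts
  out$pos_a <- as.integer(unlist(Map(lookup, out$entity_a, out$pos_a)))
  out$pos_b <- as.integer(unlist(Map(lookup, out$entity_b, out$pos_b)))
  dropped <- sum(is.na(out$pos_a) | is.na(out$pos_b))
  if (dropped > 0) {
    message(dropped, " contact(s) dropped: endpoint not mapped to target numbering")
  }
  out[!is.na(out$pos_a) & !is.na(out$pos_b), , drop = FALSE]
}

canonical_pairs <- function(contacts) {
  keep <- c("entity_a", "pos_a", "aa_a", "entity_b", "pos_b", "aa_b",
            "min_distance")
  if (nrow(contacts) == 0) return(contacts[, keep])
  swap <- with(contacts, entity_b < entity_a |
                 (entity_b == entity_a & pos_b < pos_a))
  out <- contacts
  out[swap, c("entity_a", "pos_a", "aa_a", "entity_b", "pos_b", "aa_b")] <-
    contacts[swap, c("entity_b", "pos_b", "aa_b", "entity_a", "pos_a", "aa_a")]
  out |>
    dplyr::group_by(.data$entity_a, .data$pos_a, .data$aa_a,
                    .data$entity_b, .data$pos_b, .data$aa_b) |>
    dplyr::summarise(min_distance = min(.data$min_distance), .groups = "drop")
}

#' Classify contacts by calcium state
#'
#' Compares the contact sets of a calcium-bound and a calcium-free complex
#' (both already in the same residue coordinate system) and labels each
#' residue pair as occurring only in the bound state, only in the free
#' state, or in both. The output covers the union of the two sets.
#'
#' @param bound,free Contact tibbles (columns `entity_a`, `pos_a`, `aa_a`,
#'   `entity_b`, `pos_b`, `aa_b`, `min_distance`), e.g. from
#'   [interchain_contacts()] after [renumber_contacts()].
#' @return A tibble with one row per residue pair in the union, a
#'   `state_class` column (`"bound_only"`, `"free_only"` or `"common"`), and
#'   `min_distance_bound` / `min_distance_free` columns (NA where absent).
#' @export
classify_contact_states <- function(bound, free) {
  key <- c("entity_a", "pos_a", "aa_a", "entity_b", "pos_b", "aa_b")
  b <- canonical_pairs(bound) |> dplyr::rename(min_distance_bound = "min_distance")
  f <- canonical_pairs(free) |> dplyr::rename(min_distance_free = "min_distance")
  dplyr::full_join(b, f, by = key) |>
    dplyr::mutate(state_class = dplyr::case_when(
      !is.na(.data$min_distance_bound) & !is.na(.data$min_distance_free) ~ "common",
      !is.na(.data$min_distance_bound) ~ "bound_only",
      TRUE ~ "free_only"
    )) |>
    dplyr::arrange(.data$entity_a, .data$pos_a, .data$entity_b, .data$pos_b)
}

#' Write a contact table to TSV
#'
#' @param contacts A contact tibble (optionally state-classified).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  readr::write_tsv(contacts, path)
  invisible(path)
}
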