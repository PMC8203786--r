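#' Conformer trajectory container
#'
#' An ordered set of conformer frames over a fixed atom set, the input to
#' the RMSD / RMSF / SASA metrics.
#'
#' @param frames A list of `n_atoms x 3` coordinate matrices (Angstrom), all
#'   with the same atom count and order.
#' @param meta Optional atom metadata tibble with columns `elety` (atom
#'   name), `resno`, `elesy` (element); required for named selections.
#' @param times Optional per-frame times (ns).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, meta = NULL, times = NULL) {
  stopifnot(length(frames) >= 1)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3, all(is.finite(f)))
    unname(f)
  })
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n)) {
    stop("all frames must have the same atom count")
  }
  if (!is.null(meta)) stopifnot(nrow(meta) == n)
  structure(list(frames = frames, meta = meta, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames x",
      nrow(x$frames[[1]]), "atoms\n")
  invisible(x)
}

#' Read a conformer ensemble from multi-model PDB or coordinate CSV
#'
#' Multi-model PDB files (MODEL/ENDMDL blocks) are read with every model as
#' one frame; CSV files must have columns `frame`, `atom`, `x`, `y`, `z`
#' (plus optional `elety`, `resno`, `elesy`).
#'
#' @param path File path (`.pdb` or `.csv`).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- readr::read_csv(path, show_col_types = FALSE)
    stopifnot(all(c("frame", "atom", "x", "y", "z") %in% names(d)))
    d <- dplyr::arrange(d, .data$frame, .data$atom)
    frames <- lapply(split(d, d$frame),
                     function(fd) cbind(fd$x, fd$y, fd$z))
    first <- d[d$frame == d$frame[1], , drop = FALSE]
    grab <- function(col, default) {
      if (col %in% names(first)) first[[col]] else default
    }
    meta <- tibble::tibble(
      elety = grab("elety", rep(NA_character_, nrow(first))),
      resno = grab("resno", seq_len(nrow(first))),
      elesy = grab("elesy", rep(NA_character_, nrow(first)))
    )
    return(trajectory(unname(frames), meta))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  meta <- tibble::tibble(elety = pdb$atom$elety,
                         resno = as.integer(pdb$atom$resno),
                         elesy = toupper(pdb$atom$elesy))
  trajectory(frames, meta)
}

select_atoms <- function(traj, selection = c("backbone", "calpha", "all")) {
  selection <- match.arg(selection)
  n <- nrow(traj$frames[[1]])
  if (selection == "all") return(seq_len(n))
  if (is.null(traj$meta) || all(is.na(traj$meta$elety))) {
    stop("trajectory has no atom names; selection '", selection,
         "' unavailable")
  }
  idx <- switch(selection,
    backbone = which(traj$meta$elety %in% c("N", "CA", "C", "O")),
    calpha = which(traj$meta$elety == "CA")
  )
  if (length(idx) == 0) stop("empty atom selection: ", selection)
  idx
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of one coordinate set onto another via
#' singular value decomposition, with the determinant corrected so the
#' rotation is proper (no reflection). The returned transform minimises the
#' (weighted) RMSD over all rigid motions.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, not all
#'   collinear.
#' @param weights Optional non-negative atom weights.
#' @return A list with `rotation` (3x3, det +1), `translation` (length-3),
#'   and `rmsd`; apply with [apply_superposition()] as
#'   `coords %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3) stop("need at least 3 atoms to superpose")
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)

  pbar <- colSums(P * w)
  qbar <- colSums(Q * w)
  P0 <- sweep(P, 2, pbar)
  Q0 <- sweep(Q, 2, qbar)

  sv_ref <- svd(Q0 * sqrt(w))$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    stop("degenerate (collinear) reference coordinates")
  }

  H <- t(P0 * w) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(qbar - R %*% pbar)
  aligned <- P %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix.
#' @param sp Result of [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  coords %*% t(sp$rotation) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' Per-frame RMSD from a reference frame
#'
#' Each frame is superposed onto the reference frame over the atom
#' selection and the RMSD over that selection is recorded, giving the
#' time evolution of structural deviation from a starting conformation.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Index of the reference frame (default 1).
#' @param selection `"backbone"` (N, CA, C, O), `"calpha"` or `"all"`.
#' @return A tibble with columns `frame`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1,
                        selection = c("backbone", "calpha", "all")) {
  idx <- select_atoms(traj, selection)
  ref <- traj$frames[[reference_frame]][idx, , drop = FALSE]
  rmsd <- vapply(traj$frames, function(f) {
    kabsch_superpose(f[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_along(traj$frames), rmsd = rmsd)
}

#' Per-atom root-mean-square fluctuation
#'
#' Measures the movement of each selected atom around its average position:
#' frames are superposed onto an iterated mean structure (two passes,
#' starting from the first frame as reference), then
#' `RMSF_i = sqrt(mean_f |x_fi - xbar_i|^2)`. The rigid-body fit removes
#' six degrees of freedom, which slightly shrinks apparent fluctuations;
#' for ensembles already expressed in a common frame, set
#' `superpose = FALSE` to skip the fit.
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param selection Atom selection, default `"calpha"`.
#' @param superpose Superpose frames onto the iterated mean structure first
#'   (default TRUE).
#' @return A tibble with columns `atom` (index within selection), `resno`
#'   (when metadata is available) and `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = c("calpha", "backbone", "all"),
                         superpose = TRUE) {
  if (length(traj$frames) < 2) stop("need at least two frames for RMSF")
  idx <- select_atoms(traj, selection)
  frames <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  ref <- frames[[1]]
  if (superpose) {
    for (pass in 1:2) {
      frames <- lapply(frames, function(f) {
        apply_superposition(f, kabsch_superpose(f, ref))
      })
      ref <- Reduce(`+`, frames) / length(frames)
    }
  } else {
    ref <- Reduce(`+`, frames) / length(frames)
  }
  dev2 <- Reduce(`+`, lapply(frames, function(f) rowSums((f - ref)^2)))
  tibble::tibble(
    atom = seq_along(idx),
    resno = if (!is.null(traj$meta)) traj$meta$resno[idx] else seq_along(idx),
    rmsf = sqrt(dev2 / length(frames))
  )
}

# deterministic quasi-uniform unit-sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atom spheres: each atom is covered with a
#' deterministic quasi-uniform point lattice at radius `r + probe`, and the
#' fraction of points not inside any neighbour's expanded sphere times
#' `4 pi (r + probe)^2` is its accessible area. Atoms at identical centres
#' are both retained; their lattice points lie exactly on each other's
#' expanded sphere, which the strict interior test counts as accessible, so
#' coincident duplicates each keep their full area.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom), or a character
#'   vector of element symbols looked up in [default_vdw_radii()].
#' @param probe Probe radius, default 1.4 (water).
#' @param n_points Lattice points per atom, default 960; at least 100.
#' @return A tibble with columns `atom`, `radius`, `area` (Angstrom^2) and
#'   attribute `total`; see also [sasa_total()].
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.character(radii)) {
    tab <- default_vdw_radii()
    r <- unname(tab[toupper(radii)])
    r[is.na(r)] <- 1.70
  } else {
    r <- rep_len(radii, n)
  }
  stopifnot(all(r > 0), probe >= 0, n_points >= 100)
  pts <- sphere_points(n_points)
  R <- r + probe
  area <- numeric(n)
  d2mat <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2mat[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- pts * R[i] + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, coords[j, ])^2)
      buried <- dj2 < R[j]^2 - 1e-9
      acc[acc] <- !buried
    }
    area[i] <- mean(acc) * 4 * pi * R[i]^2
  }
  out <- tibble::tibble(atom = seq_len(n), radius = r, area = area)
  attr(out, "total") <- sum(area)
  out
}

#' @rdname sasa
#' @param ... Passed to [sasa()].
#' @export
sasa_total <- function(coords, radii, ...) {
  attr(sasa(coords, radii, ...), "total")
}

#' Per-frame total SASA of a trajectory
#'
#' @param traj A [trajectory()] with element metadata (or explicit radii).
#' @param radii Optional per-atom radii; defaults to an element lookup in
#'   [default_vdw_radii()].
#' @inheritParams sasa
#' @return A tibble with columns `frame`, `area`.
#' @export
sasa_series <- function(traj, radii = NULL, probe = 1.4, n_points = 960) {
  if (is.null(radii)) {
    if (is.null(traj$meta) || all(is.na(traj$meta$elesy))) {
      stop("no element metadata; supply radii explicitly")
    }
    radii <- traj$meta$elesy
  }
  tibble::tibble(
    frame = seq_along(traj$frames),
    area = vapply(traj$frames, function(f) {
      attr(sasa(f, radii, probe = probe, n_points = n_points), "total")
    }, numeric(1))
  )
}

#' Van der Waals radii table
#'
#' The Bondi (1964) radii shipped with the package as a plain-text config
#' file, used for SASA by element symbol. Unknown elements fall back to
#' 1.70 (carbon).
#'
#' @return Named numeric vector of radii (Angstrom) keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.tsv", package = "thinfilament",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", na.strings = NULL,
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$radius, toupper(tab$element))
}
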