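#' Region schemes for thin-filament proteins
#'
#' A region scheme is a set of named, non-overlapping, inclusive residue
#' intervals for one protein, plus optional explicitly excluded intervals.
#' The default troponin T scheme partitions the 288-residue adult cardiac
#' isoform into four analysis regions (1-89, 90-129, 130-179, 200-288) with
#' residues 180-199 excluded: that stretch lacks the structural interaction
#' data that define the other regions, so cases there are never analysed.
#' The default troponin I scheme is 1-130, 131-175, 176-210.
#'
#' @param entity Protein entity name (e.g. `"TnT"`).
#' @param regions A data frame with columns `label`, `start`, `end`
#'   (inclusive, 1-based).
#' @param excluded Optional data frame with columns `start`, `end` of
#'   explicitly excluded intervals.
#' @return A tibble with columns `label`, `start`, `end`, `type`
#'   (`"region"` or `"excluded"`), class `region_scheme`, and an `entity`
#'   attribute.
#' @export
region_scheme <- function(entity, regions, excluded = NULL) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("label", "start", "end") %in% names(regions)))
  out <- dplyr::mutate(regions, type = "region")
  if (!is.null(excluded)) {
    excluded <- tibble::as_tibble(excluded)
    if (!"label" %in% names(excluded)) excluded$label <- "excluded"
    out <- dplyr::bind_rows(out, dplyr::mutate(excluded, type = "excluded"))
  }
  out <- dplyr::arrange(out, .data$start)
  if (any(out$start > out$end)) stop("interval with start > end")
  if (nrow(out) > 1 && any(out$start[-1] <= out$end[-nrow(out)])) {
    stop("overlapping intervals in region scheme")
  }
  attr(out, "entity") <- entity
  class(out) <- c("region_scheme", class(out))
  out
}

#' @rdname region_scheme
#' @export
tnt_regions <- function() {
  region_scheme(
    "TnT",
    tibble::tibble(label = c("1-89", "90-129", "130-179", "200-288"),
                   start = c(1L, 90L, 130L, 200L),
                   end = c(89L, 129L, 179L, 288L)),
    excluded = tibble::tibble(start = 180L, end = 199L)
  )
}

#' @rdname region_scheme
#' @export
tni_regions <- function() {
  region_scheme(
    "TnI",
    tibble::tibble(label = c("1-130", "131-175", "176-210"),
                   start = c(1L, 131L, 176L),
                   end = c(130L, 175L, 210L))
  )
}

#' Assign residue positions to regions
#'
#' @param scheme A [region_scheme()].
#' @param position Integer vector of 1-based residue positions.
#' @return Character vector: the region label, `"excluded"` for positions in
#'   an excluded interval, or `"outside"` for positions in no interval.
#' @export
assign_region <- function(scheme, position) {
  stopifnot(inherits(scheme, "region_scheme"))
  if (any(is.na(position)) || any(position < 1)) {
    stop("positions must be >= 1 and non-missing")
  }
  out <- rep("outside", length(position))
  for (i in seq_len(nrow(scheme))) {
    hit <- position >= scheme$start[i] & position <= scheme$end[i]
    out[hit] <- if (scheme$type[i] == "excluded") "excluded" else scheme$label[i]
  }
  out
}

#' High/low-risk strata over troponin T regions
#'
#' The survival analysis groups the TnT regions into a high-risk stratum
#' (90-129 and 130-179) and a low-risk stratum (1-89 and 200-288). The upper
#' bound of the second high-risk region is 179, consistent with the region
#' scheme.
#'
#' @return Named character vector mapping region label to `"high"`/`"low"`.
#' @export
tnt_risk_strata <- function() {
  c(`90-129` = "high", `130-179` = "high", `1-89` = "low", `200-288` = "low")
}
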