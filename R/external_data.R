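#' Load the curated literature case table
#'
#' The clinical analyses were designed around a curated, literature-derived
#' table of troponin variant carriers (per case: gene, amino-acid
#' substitution, index/relative flag, phenotype, last follow-up age,
#' cause-specific event flags, number of pathogenic variants). That table is
#' distributed with its source publication, not with this package; download
#' it, convert it to the case-table schema documented in [read_cases()],
#' and place it at `inst/extdata/published_troponin_cases.csv` (or pass a
#' path). Synthetic cohorts with the same schema are available from
#' [simulate_cohort()].
#'
#' @param path Optional explicit path to the CSV.
#' @return A case tibble (see [read_cases()]).
#' @export
published_case_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_troponin_cases.csv",
                        package = "thinfilament")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("curated case table not found; download the published ",
         "supplementary case listing, convert it to the read_cases() ",
         "schema and save it as inst/extdata/published_troponin_cases.csv")
  }
  read_cases(path)
}

#' Load the canonical adult cardiac TNNT2 coding sequence
#'
#' The arginine/CpG codon census targets the canonical 288-residue adult
#' cardiac troponin T isoform (UniProt P45379). Its coding sequence is not
#' redistributed with this package; fetch it (e.g. from Ensembl/RefSeq for
#' the P45379-ME isoform), save it as FASTA at
#' `inst/extdata/tnnt2_cds.fasta`, or pass a path.
#'
#' @param path Optional explicit path to a single-record CDS FASTA.
#' @return A [gene_model()] for TNNT2.
#' @export
tnnt2_gene_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tnnt2_cds.fasta",
                        package = "thinfilament")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("TNNT2 CDS not found; fetch the coding sequence of the ",
         "288-residue adult cardiac isoform (UniProt P45379) and save it ",
         "as inst/extdata/tnnt2_cds.fasta")
  }
  ss <- Biostrings::readDNAStringSet(path)
  gene_model("TNNT2", as.character(ss[[1]]))
}
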