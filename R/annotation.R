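#' Load an offline probe annotation table
#'
#' Reads a TSV mapping probe IDs to rsIDs and gene symbols (the offline
#' stand-in for the platform vendor's annotation library). Required column:
#' `probe_id`; optional: `rsid`, `gene`, `note`. Unknown columns are
#' ignored; a malformed rsid (not `rs` followed by digits) is blanked with
#' a warning.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of class `dmet_annotation` with columns `probe_id`,
#'   `rsid`, `gene`, `note`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"probe_id" %in% names(ann)) {
    abort("Annotation file must have a `probe_id` column.",
          class = "dmetr_format_error")
  }
  if (anyDuplicated(ann$probe_id)) {
    abort(paste0("Duplicate probe_id in annotation: ",
                 paste(unique(ann$probe_id[duplicated(ann$probe_id)]),
                       collapse = ", ")),
          class = "dmetr_validation_error")
  }
  for (col in c("rsid", "gene", "note")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  ann <- ann[, c("probe_id", "rsid", "gene", "note")]
  ann[is.na(ann)] <- ""
  bad_rs <- nzchar(ann$rsid) & !grepl("^rs[0-9]+$", ann$rsid)
  if (any(bad_rs)) {
    warn(paste0("Malformed rsid blanked for probe(s): ",
                paste(ann$probe_id[bad_rs], collapse = ", ")))
    ann$rsid[bad_rs] <- ""
  }
  tibble::new_tibble(ann, class = "dmet_annotation")
}

#' dbSNP reference page for an rsID
#'
#' Deterministic, purely syntactic URL construction; no network access.
#'
#' @param rsid Character vector of rsIDs matching `rs[0-9]+`.
#' @return Character vector of `https://www.ncbi.nlm.nih.gov/snp/...` URLs.
#' @examples
#' dbsnp_url("rs10893")
#' @export
dbsnp_url <- function(rsid) {
  if (any(!grepl("^rs[0-9]+$", rsid))) {
    abort(paste0("Not a valid rsID: ",
                 paste(rsid[!grepl("^rs[0-9]+$", rsid)], collapse = ", ")),
          class = "dmetr_domain_error")
  }
  paste0("https://www.ncbi.nlm.nih.gov/snp/", rsid)
}

#' PharmGKB search link for an rsID or gene symbol
#'
#' @param query Character vector of non-empty search terms (rsIDs or gene
#'   symbols); URL-encoded into a PharmGKB search URL. Syntactic only.
#' @return Character vector of `https://www.pharmgkb.org/search?query=...`.
#' @examples
#' pharmgkb_url(c("ABCC5", "rs2097937"))
#' @export
pharmgkb_url <- function(query) {
  if (any(!nzchar(query)) || any(is.na(query))) {
    abort("PharmGKB query must be non-empty.", class = "dmetr_domain_error")
  }
  vapply(query, function(q) {
    paste0("https://www.pharmgkb.org/search?query=",
           URLencode(q, reserved = TRUE))
  }, character(1), USE.NAMES = FALSE)
}

#' Attach rsID, gene and database links to association results
#'
#' Best-effort left join: probes found in the annotation store gain `rsid`,
#' `gene`, `dbsnp_url` and `pharmgkb_url` columns; probes absent from the
#' store pass through with empty annotation and are never dropped. P-values,
#' counts and row order are untouched.
#'
#' @param results A `dmet_assoc` tibble (or any data frame with a
#'   `probe_id` column).
#' @param annotation A `dmet_annotation` store from [read_annotation()].
#' @return `results` with four annotation columns appended.
#' @export
annotate_results <- function(results, annotation) {
  ann <- annotation[, c("probe_id", "rsid", "gene")]
  idx <- match(results$probe_id, ann$probe_id)
  rsid <- ifelse(is.na(idx), "", ann$rsid[idx])
  gene <- ifelse(is.na(idx), "", ann$gene[idx])
  out <- results
  out$rsid <- rsid
  out$gene <- gene
  out$dbsnp_url <- ifelse(nzchar(rsid), paste0("https://www.ncbi.nlm.nih.gov/snp/", rsid), "")
  query <- ifelse(nzchar(rsid), rsid, gene)
  out$pharmgkb_url <- ifelse(nzchar(query),
                             vapply(query, function(q) {
                               if (!nzchar(q)) return("")
                               paste0("https://www.pharmgkb.org/search?query=",
                                      URLencode(q, reserved = TRUE))
                             }, character(1), USE.NAMES = FALSE),
                             "")
  out
}
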