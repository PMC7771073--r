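#' Read a transcript quantification table
#'
#' Reads a tab-delimited quantification table of the sailfish/salmon kind:
#' a header line naming an id column and a TPM column, one row per transcript.
#' Values are returned verbatim; no expression threshold is applied at read
#' time (the `TPM > 1` rule belongs to the caller, not the reader).
#'
#' @param path tab-delimited file with a header.
#' @param id_col,tpm_col column names; by default the first of
#'   `Name`/`transcript_id`/`Transcript`/`id` present is the id column and the
#'   first column whose name matches `TPM` (case-insensitive) is the value.
#' @return named numeric vector of TPM keyed by transcript id.
#' @export
read_quant_table <- function(path, id_col = NULL, tpm_col = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(id_col)) {
    cand <- c("Name", "name", "transcript_id", "Transcript", "id", "ID")
    id_col <- cand[cand %in% names(tab)][1]
    if (is.na(id_col)) id_col <- names(tab)[1]
  }
  if (is.null(tpm_col)) {
    hit <- which(toupper(names(tab)) == "TPM")
    if (length(hit) == 0) {
      stop("no TPM column found; available columns: ",
           paste(names(tab), collapse = ", "))
    }
    tpm_col <- names(tab)[hit[1]]
  }
  if (!tpm_col %in% names(tab)) {
    stop("no TPM column found; available columns: ",
         paste(names(tab), collapse = ", "))
  }
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated transcript id in quantification table: ",
         ids[duplicated(ids)][1])
  }
  tpm <- as.numeric(tab[[tpm_col]])
  if (anyNA(tpm)) stop("non-numeric TPM value in quantification table")
  names(tpm) <- ids
  tpm
}
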