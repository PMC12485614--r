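# Ancestral site table and template editing. The table is the bridge
# between the per-site reconstructions and both the FASTA editor and the
# polarizer: one row per reconstructed position with the template and
# ancestral alleles, a converted flag and the uncertainty score.

.read_fasta_keepcase <- function(x) {
  if (methods::is(x, "XStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(as.character(Biostrings::readBStringSet(x)))
  if (is.character(x)) return(x)  # named character vector of sequences
  stop("template must be a FASTA path, an XStringSet or a character vector")
}

#' Build the ancestral site table
#'
#' Joins per-site reconstructions with the template sequence: a site is
#' flagged `converted` exactly when its reconstruction succeeded
#' (status `"OK"`) and the ancestral allele differs from the template
#' base. Sites whose template base is N or another ambiguity code are
#' never converted and carry status `"SKIPPED_TEMPLATE_AMBIGUOUS"`;
#' TIE / INSUFFICIENT_DATA sites are carried through unconverted so
#' downstream tools can see (and filter on) them.
#'
#' @param recons Data frame from [wmp_reconstruct_sites()] (needs
#'   columns `position`, `ancestral`, `status`, `uncertainty`).
#' @param template Template chromosome: FASTA path, `XStringSet`, or a
#'   character string; the first record is used.
#' @return Data frame of class `ancestral_site_table` with columns
#'   `position`, `template`, `ancestral`, `converted`, `uncertainty`,
#'   `status`, sorted by unique position.
#' @export
build_site_table <- function(recons, template) {
  stopifnot(all(c("position", "ancestral", "status") %in% names(recons)))
  seqs <- .read_fasta_keepcase(template)
  seq1 <- seqs[[1]]
  if (anyDuplicated(recons$position))
    stop("duplicated positions in reconstruction table")
  recons <- recons[order(recons$position), , drop = FALSE]
  if (any(recons$position < 1 | recons$position > nchar(seq1)))
    stop("position(s) outside the template sequence")

  tmpl <- toupper(substring(seq1, recons$position, recons$position))
  status <- recons$status
  status[!tmpl %in% NUC] <- "SKIPPED_TEMPLATE_AMBIGUOUS"
  converted <- status == "OK" & !is.na(recons$ancestral) &
    tmpl != recons$ancestral

  out <- data.frame(position = recons$position,
                    template = tmpl,
                    ancestral = recons$ancestral,
                    converted = converted,
                    uncertainty = if ("uncertainty" %in% names(recons))
                      recons$uncertainty else NA_real_,
                    status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("ancestral_site_table", class(out))
  out
}

#' Write / read an ancestral site table as TSV
#'
#' Header columns: `position template ancestral converted uncertainty
#' status`.
#'
#' @param table An `ancestral_site_table`.
#' @param path Output TSV path.
#' @return `write_site_table` returns `path` invisibly;
#'   `read_site_table` returns the table.
#' @export
write_site_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(position = "numeric",
                                   template = "character",
                                   ancestral = "character",
                                   converted = "logical",
                                   uncertainty = "numeric",
                                   status = "character"))
  class(out) <- c("ancestral_site_table", class(out))
  out
}

#' Edit a template FASTA into the ancestral-like reference
#'
#' Replaces the template base with the reconstructed ancestral allele at
#' every `converted` site of the table. The edited record keeps its
#' length; soft-masked (lowercase) bases elsewhere keep their case,
#' while converted positions are written uppercase. All other records of
#' a multi-record FASTA pass through unaltered. As a guard against stale
#' tables, the base actually present in the template must match the
#' table's `template` allele (case-insensitively) at every converted
#' site; a mismatch is a hard error naming the position.
#'
#' @param template FASTA path, `XStringSet` or character vector; may
#'   contain several records.
#' @param table An `ancestral_site_table` (or data frame with the same
#'   columns).
#' @param record Name or index of the record to edit (default: first).
#' @param out Optional output FASTA path; written 60 columns wide.
#' @return The edited sequences as a [Biostrings::BStringSet]
#'   (invisibly if `out` is given).
#' @export
apply_to_fasta <- function(template, table, record = 1L, out = NULL) {
  seqs <- .read_fasta_keepcase(template)
  if (is.character(record)) {
    if (!record %in% names(seqs)) stop("no FASTA record named '", record, "'")
    rec <- match(record, names(seqs))
  } else rec <- as.integer(record)
  s <- seqs[[rec]]

  edit <- table[table$converted %in% TRUE, , drop = FALSE]
  if (nrow(edit)) {
    if (any(edit$position < 1 | edit$position > nchar(s)))
      stop("converted position(s) outside the target sequence")
    have <- toupper(substring(s, edit$position, edit$position))
    bad <- have != toupper(edit$template)
    if (any(bad))
      stop("template allele mismatch at position ",
           edit$position[which(bad)[1]], ": table says ",
           edit$template[which(bad)[1]], ", sequence has ",
           have[which(bad)[1]],
           " (was the table built against this template?)")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[edit$position] <- toupper(edit$ancestral)
    s <- paste(ch, collapse = "")
  }
  seqs[[rec]] <- s
  res <- Biostrings::BStringSet(seqs)
  if (!is.null(out)) {
    Biostrings::writeXStringSet(res, out, width = 60L)
    return(invisible(res))
  }
  res
}
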