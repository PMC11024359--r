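# FASTA / TSV input and output, plus CrusTome-style header parsing.
#
# FASTA parsing and writing are delegated to Biostrings; validation of the
# residue alphabet, the partial-sequence header convention and transcriptome
# identifier metadata are owned here so that errors name the offending record
# and position.

# CrusTome transcript ids look like "GeclaM_EVm001193t2" (optionally with a
# "/2" fragment suffix); the species code is the prefix before the first "_".
.crustome_pattern <- "^([A-Za-z0-9]+)_[Ee][Vv]m[0-9]+t[0-9]+(/[0-9]+)?$"

#' Construct a protein sequence record
#'
#' @param id Unique sequence identifier (no trailing partial marker).
#' @param residues Uppercase residue string over the 20 amino acids plus `X`.
#'   Gaps are not allowed in an unaligned record.
#' @param is_partial Logical; `TRUE` when the record is known to be an
#'   incomplete open reading frame (the paper-style trailing `"*"`).
#' @param species_code Species prefix parsed from a CrusTome-style id, or `""`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, is_partial = FALSE, species_code = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(residues)
  .check_residues(residues, id, alphabet = .seq_alphabet)
  if (is.null(species_code)) {
    species_code <- if (grepl(.crustome_pattern, id)) sub("_.*$", "", id) else ""
  }
  structure(list(id = id, species_code = species_code,
                 residues = residues, is_partial = isTRUE(is_partial)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s%s (%d aa)%s\n", x$id,
              if (x$is_partial) " [partial]" else "",
              nchar(x$residues),
              if (nzchar(x$species_code)) paste0(" species=", x$species_code) else ""))
  invisible(x)
}

.check_residues <- function(residues, id, alphabet) {
  if (!nzchar(residues)) stop("record '", id, "': empty sequence", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop("record '", id, "': illegal residue character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a protein FASTA file into sequence records
#'
#' Headers are parsed for CrusTome-style metadata: the species code is the
#' prefix before the first underscore when the id matches the transcriptome
#' naming convention, otherwise empty.  A record is flagged partial when the
#' header carries a trailing `partial_token` (stripped from the id) or a
#' whitespace-separated `"partial"` tag.
#'
#' @param path Path to a protein FASTA file (wrapped or unwrapped).
#' @param partial_token Header token marking partial sequences (default `"*"`).
#' @param strict When `TRUE` (default) any invalid record aborts with an error;
#'   when `FALSE` invalid records are dropped and reported via the
#'   `"errors"` attribute, so that records read + errors = entries in file.
#' @return List of [seq_record()] objects (attribute `"errors"`: character
#'   vector of per-record messages when `strict = FALSE`).
#' @export
read_fasta <- function(path, partial_token = "*", strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  records <- vector("list", length(set))
  errors <- character(0)
  seen <- character(0)
  for (i in seq_along(set)) {
    header <- headers[i]
    fields <- strsplit(trimws(header), "[ \t]+")[[1L]]
    id <- if (length(fields)) fields[1L] else ""
    is_partial <- any(tolower(fields[-1]) == "partial")
    if (nzchar(partial_token) && endsWith(id, partial_token)) {
      is_partial <- TRUE
      id <- substr(id, 1L, nchar(id) - nchar(partial_token))
    }
    res <- tryCatch(
      seq_record(id, as.character(set[[i]]), is_partial = is_partial),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      if (strict) stop(res, call. = FALSE)
      errors <- c(errors, res)
      next
    }
    if (res$id %in% seen) {
      msg <- paste0("duplicate sequence id '", res$id, "'")
      if (strict) stop(msg, call. = FALSE)
      errors <- c(errors, msg)
      next
    }
    seen <- c(seen, res$id)
    records[[i]] <- res
  }
  records <- Filter(Negate(is.null), records)
  attr(records, "errors") <- errors
  records
}

#' Write sequence records to a protein FASTA file
#'
#' Partial records are written with the trailing partial marker so that
#' `write_fasta` followed by [read_fasta()] is the identity.
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param partial_token Marker appended to ids of partial records.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, partial_token = "*", width = 60L) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  headers <- ifelse(vapply(records, function(r) r$is_partial, logical(1)),
                    paste0(ids, partial_token), ids)
  set <- Biostrings::BStringSet(vapply(records, function(r) r$residues, character(1)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a grouped alignment
#'
#' @param rows Named character vector of aligned rows (names = sequence ids;
#'   characters over the 20 amino acids, `X` and `-`), all the same length.
#' @param group_of Named character vector mapping every row id to a group label.
#' @return Object of class `grouped_alignment` with elements `rows`,
#'   `group_of`, `ncol`, `groups`.
#' @export
grouped_alignment <- function(rows, group_of) {
  stopifnot(is.character(rows), !is.null(names(rows)),
            is.character(group_of), !is.null(names(group_of)))
  if (anyDuplicated(names(rows))) stop("duplicate row ids", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  rows <- toupper(rows)
  for (id in names(rows)) .check_residues(rows[[id]], id, alphabet = .aln_alphabet)
  missing <- setdiff(names(rows), names(group_of))
  if (length(missing)) {
    stop("rows missing a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  group_of <- group_of[names(rows)]
  structure(list(rows = rows, group_of = group_of,
                 ncol = unname(widths[1L]),
                 groups = sort(unique(unname(group_of)))),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("<grouped_alignment> %d rows x %d columns, %d groups (%s)\n",
              length(x$rows), x$ncol, length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Read an aligned FASTA plus a group-label TSV
#'
#' @param path Aligned protein FASTA (rows must be equal length).
#' @param groups_path TSV with header columns `id` and `group`.
#' @return A [grouped_alignment()].
#' @export
read_alignment <- function(path, groups_path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  rows <- as.character(set)
  names(rows) <- vapply(strsplit(trimws(names(set)), "[ \t]+"),
                        `[`, character(1), 1L)
  tab <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(tab))) {
    stop("groups TSV must have 'id' and 'group' columns", call. = FALSE)
  }
  group_of <- stats::setNames(as.character(tab$group), as.character(tab$id))
  grouped_alignment(rows, group_of)
}

#' Read a domain-annotation TSV
#'
#' Expects header columns `seq_id`, `domain`, `start`, `end` with 1-based
#' inclusive coordinates (the convention of conserved-domain search exports).
#' Domain labels outside the controlled vocabulary are kept but flagged
#' (`known = FALSE`).
#'
#' @param path Path to the TSV.
#' @return Named list: per sequence id, a data frame with columns `domain`,
#'   `start`, `end`, `known`, sorted by `start`.
#' @export
read_domains <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "domain", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("domains TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("start", "end")) {
    v <- tab[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      stop("non-integer coordinate in column '", col, "'", call. = FALSE)
    }
    tab[[col]] <- as.integer(v)
  }
  bad <- which(tab$start > tab$end | tab$start < 1L)
  if (length(bad)) {
    stop("invalid domain coordinates for '", tab$seq_id[bad[1L]], "': start ",
         tab$start[bad[1L]], " > end ", tab$end[bad[1L]], call. = FALSE)
  }
  tab$domain <- toupper(tab$domain)
  tab$known <- tab$domain %in% .domain_vocab
  out <- split(tab[, c("domain", "start", "end", "known")], tab$seq_id)
  lapply(out, function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
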