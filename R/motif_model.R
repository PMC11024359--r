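# Degenerate consensus motifs and the kinase-domain landmarks.
#
# A motif is an ungapped, fixed-length pattern: each position is either a
# fixed residue set (usually a singleton) or the wildcard 'x'.  Scoring counts
# fixed positions only; wildcards contribute to neither numerator nor
# denominator, and an ambiguous X in the subject never matches a fixed
# position.  Universal positions (the bold residues of the published tables,
# identical across all subtypes of a class) are tracked separately so a caller
# can demand them intact while tolerating mismatches elsewhere.

#' Compile a degenerate consensus motif
#'
#' The consensus syntax is one character per position: an uppercase amino acid
#' for a fixed position, `x` for a wildcard, or a bracketed residue set such as
#' `[GR]` for a fixed position admitting several residues.
#'
#' @param consensus Consensus string (e.g. `"VHRDLAARNC"`, `"GxGxFG"`,
#'   `"H[GR]DLA"`).
#' @param bold_positions Integer vector of 1-based positions that are
#'   universally conserved across all subtypes of the class.  Must point at
#'   fixed singleton positions.
#' @param name Motif name.
#' @param rtk_class,subtype Optional receptor class / subtype labels.
#' @param source Free-text provenance note.
#' @return An object of class `degenerate_motif` with elements `name`,
#'   `rtk_class`, `subtype`, `consensus`, `positions` (list; `NULL` =
#'   wildcard), `universal_mask`, `fixed_total`, `length`, `source`.
#' @export
compile_motif <- function(consensus, bold_positions = integer(), name = consensus,
                          rtk_class = NA_character_, subtype = NA_character_,
                          source = NA_character_) {
  stopifnot(is.character(consensus), length(consensus) == 1L, nzchar(consensus))
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      positions[length(positions) + 1L] <- list(NULL)  # wildcard slot
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > length(chars) || length(set) == 0L) {
        stop("motif '", name, "': unterminated or empty bracket set", call. = FALSE)
      }
      if (!all(set %in% AA20)) {
        stop("motif '", name, "': illegal residue in bracket set", call. = FALSE)
      }
      positions[[length(positions) + 1L]] <- set
      i <- j + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("motif '", name, "': character '", ch,
           "' outside the motif alphabet", call. = FALSE)
    }
  }
  is_fixed <- !vapply(positions, is.null, logical(1))
  if (!any(is_fixed)) {
    stop("motif '", name, "': no fixed position", call. = FALSE)
  }
  n <- length(positions)
  bold_positions <- as.integer(bold_positions)
  if (length(bold_positions)) {
    if (any(bold_positions < 1L | bold_positions > n)) {
      stop("motif '", name, "': bold position out of range", call. = FALSE)
    }
    singleton <- is_fixed & vapply(positions, function(p) length(p) == 1L, logical(1))
    if (!all(singleton[bold_positions])) {
      stop("motif '", name,
           "': bold position must be a fixed single-residue position", call. = FALSE)
    }
  }
  universal_mask <- logical(n)
  universal_mask[bold_positions] <- TRUE
  structure(list(name = name, rtk_class = rtk_class, subtype = subtype,
                 consensus = consensus, positions = positions,
                 universal_mask = universal_mask,
                 fixed_total = sum(is_fixed), length = n, source = source),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s (%s/%s): %s  [%d positions, %d fixed, %d universal]\n",
              x$name, x$rtk_class, x$subtype, x$consensus, x$length,
              x$fixed_total, sum(x$universal_mask)))
  invisible(x)
}

.motif_match <- function(motif, start, score, fixed_matched, universal_ok) {
  structure(list(motif_name = motif$name, start = start,
                 end = start + motif$length, score = score,
                 fixed_matched = fixed_matched, fixed_total = motif$fixed_total,
                 universal_ok = universal_ok),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("<motif_match> %s @ [%d,%d) score %.3f (%d/%d fixed)%s\n",
              x$motif_name, x$start, x$end, x$score, x$fixed_matched,
              x$fixed_total, if (x$universal_ok) " universal" else ""))
  invisible(x)
}

#' Score a motif against a subject at one offset
#'
#' @param seq A [seq_record()] or residue string.
#' @param motif A [compile_motif()] object.
#' @param offset 0-based offset; must satisfy
#'   `0 <= offset <= length(seq) - length(motif)`.
#' @return A `motif_match` (`start`/`end` 0-based half-open; `score` the
#'   fraction of fixed positions matched; `universal_ok` `TRUE` iff every
#'   universal position matched).
#' @export
match_at <- function(seq, motif, offset) {
  chars <- as_residues(seq)
  n <- length(chars)
  if (offset < 0L || offset > n - motif$length) {
    stop("offset ", offset, " out of range for sequence of length ", n,
         " and motif of length ", motif$length, call. = FALSE)
  }
  matched <- 0L
  universal_ok <- TRUE
  for (j in seq_len(motif$length)) {
    allowed <- motif$positions[[j]]
    if (is.null(allowed)) next
    hit <- chars[offset + j] %in% allowed  # subject 'X' is never in `allowed`
    matched <- matched + hit
    if (motif$universal_mask[j] && !hit) universal_ok <- FALSE
  }
  .motif_match(motif, as.integer(offset), matched / motif$fixed_total,
               matched, universal_ok)
}

# Vectorised per-window fixed-match counts for all offsets; returns a list
# with integer vectors `matched` and `universal_matched` (index i = offset i-1).
.scan_counts <- function(chars, motif) {
  n_off <- length(chars) - motif$length + 1L
  if (n_off < 1L) return(list(matched = integer(0), universal_matched = integer(0)))
  matched <- integer(n_off)
  universal <- integer(n_off)
  base <- seq_len(n_off) - 1L
  for (j in seq_len(motif$length)) {
    allowed <- motif$positions[[j]]
    if (is.null(allowed)) next
    sub <- chars[base + j]
    hit <- if (length(allowed) == 1L) sub == allowed else sub %in% allowed
    matched <- matched + hit
    if (motif$universal_mask[j]) universal <- universal + hit
  }
  list(matched = matched, universal_matched = universal)
}

#' Scan a motif along a sequence
#'
#' Every window with score at least `min_score` is returned, sorted by score
#' (descending) then start (ascending).  A subject shorter than the motif
#' yields an empty list (not an error).
#'
#' @inheritParams match_at
#' @param min_score Minimum fraction of fixed positions matched, in `[0, 1]`.
#' @return List of `motif_match` objects.
#' @export
scan_motif <- function(seq, motif, min_score = 0) {
  stopifnot(min_score >= 0, min_score <= 1)
  chars <- as_residues(seq)
  counts <- .scan_counts(chars, motif)
  if (!length(counts$matched)) return(list())
  scores <- counts$matched / motif$fixed_total
  n_universal <- sum(motif$universal_mask)
  keep <- which(scores >= min_score)
  keep <- keep[order(-scores[keep], keep)]
  lapply(keep, function(i) {
    .motif_match(motif, i - 1L, scores[i], counts$matched[i],
                 counts$universal_matched[i] == n_universal)
  })
}

# best (max-score, leftmost) window score of a motif over a sequence; returns
# a motif_match or NULL when the sequence is shorter than the motif.
.best_match <- function(chars, motif) {
  counts <- .scan_counts(chars, motif)
  if (!length(counts$matched)) return(NULL)
  i <- which.max(counts$matched)
  .motif_match(motif, i - 1L, counts$matched[i] / motif$fixed_total,
               counts$matched[i],
               counts$universal_matched[i] == sum(motif$universal_mask))
}

#' Pair of bounding anchors with interior-length constraints
#'
#' @param n_anchor,c_anchor [compile_motif()] objects for the N- and C-terminal
#'   anchors (e.g. `VAVK` / `HRDLA` for the FGFR catalytic-domain motif region,
#'   `HGDLA` / `PxKW` for the PVR region).
#' @param gap_min,gap_max Bounds (inclusive) on the number of residues strictly
#'   between the two anchors.
#' @return An `anchor_pair` object.
#' @export
anchor_pair <- function(n_anchor, c_anchor, gap_min, gap_max) {
  stopifnot(inherits(n_anchor, "degenerate_motif"),
            inherits(c_anchor, "degenerate_motif"),
            gap_min <= gap_max)
  structure(list(n_anchor = n_anchor, c_anchor = c_anchor,
                 gap_min = as.integer(gap_min), gap_max = as.integer(gap_max)),
            class = "anchor_pair")
}

#' Locate anchored catalytic-domain regions
#'
#' Finds every pairing of a full (score 1) `n_anchor` match with the closest
#' downstream full `c_anchor` match whose interior length lies within the
#' anchor pair's bounds (innermost pairing).
#'
#' @param seq A [seq_record()] or residue string.
#' @param anchors An [anchor_pair()].
#' @return Data frame with 0-based half-open `start`/`end` of the full region
#'   (anchors included) and `interior` length; zero rows when no pair
#'   qualifies.
#' @export
find_anchored_region <- function(seq, anchors) {
  chars <- as_residues(seq)
  n_hits <- .full_match_starts(chars, anchors$n_anchor)
  c_hits <- .full_match_starts(chars, anchors$c_anchor)
  out <- data.frame(start = integer(0), end = integer(0), interior = integer(0))
  if (!length(n_hits) || !length(c_hits)) return(out)
  for (ns in n_hits) {
    n_end <- ns + anchors$n_anchor$length
    downstream <- c_hits[c_hits >= n_end]
    if (!length(downstream)) next
    cs <- downstream[1L]                       # innermost pairing
    interior <- cs - n_end
    if (interior >= anchors$gap_min && interior <= anchors$gap_max) {
      out <- rbind(out, data.frame(start = ns,
                                   end = cs + anchors$c_anchor$length,
                                   interior = interior))
    }
  }
  out
}

# 0-based starts of all full-score windows
.full_match_starts <- function(chars, motif) {
  counts <- .scan_counts(chars, motif)
  which(counts$matched == motif$fixed_total) - 1L
}

#' The shared kinase-domain landmark motifs
#'
#' All four receptor classes share a glycine-rich loop (`GxGxFG`), a catalytic
#' loop carrying `HRDLA` (`HGDLA` in the PVR class, hence the `H[GR]DLA`
#' pattern), and a `DFG` motif near the activation loop, in that N-to-C order.
#'
#' @return Named list of [compile_motif()] objects: `gly_loop`,
#'   `catalytic_loop`, `dfg`.
#' @export
landmark_motifs <- function() {
  list(
    gly_loop = compile_motif("GxGxFG", bold_positions = c(1, 3, 5, 6),
                             name = "gly_loop", source = "shared kinase landmark"),
    catalytic_loop = compile_motif("H[GR]DLA", bold_positions = c(1, 3, 4, 5),
                                   name = "catalytic_loop",
                                   source = "shared kinase landmark"),
    dfg = compile_motif("DFG", bold_positions = 1:3, name = "dfg",
                        source = "shared kinase landmark")
  )
}

#' Locate the three shared kinase landmarks
#'
#' Searches for full matches of the glycine-rich loop, the catalytic loop and
#' the DFG motif.  When at least one order-consistent triple exists (glycine
#' loop before catalytic loop before DFG, within the spacing bounds) the
#' left-most such triple is reported with `ordering_ok = TRUE`; otherwise each
#' landmark's first full match (if any) is reported independently with
#' `ordering_ok = FALSE`.
#'
#' @param seq A [seq_record()] or residue string.
#' @param gly_cat_gap Allowed residue count between glycine-loop end and
#'   catalytic-loop start.
#' @param cat_dfg_gap Allowed residue count between catalytic-loop end and DFG
#'   start.
#' @return Object of class `kinase_landmarks`: `gly_loop`, `catalytic_loop`,
#'   `dfg` (each a `motif_match` or `NULL`) and `ordering_ok`.
#' @export
locate_kinase_landmarks <- function(seq, gly_cat_gap = c(5L, 400L),
                                    cat_dfg_gap = c(1L, 200L)) {
  chars <- as_residues(seq)
  motifs <- landmark_motifs()
  gly_s <- .full_match_starts(chars, motifs$gly_loop)
  cat_s <- .full_match_starts(chars, motifs$catalytic_loop)
  dfg_s <- .full_match_starts(chars, motifs$dfg)

  best <- NULL
  for (g in gly_s) {
    g_end <- g + motifs$gly_loop$length
    cands_c <- cat_s[cat_s - g_end >= gly_cat_gap[1L] &
                     cat_s - g_end <= gly_cat_gap[2L]]
    for (cc in cands_c) {
      c_end <- cc + motifs$catalytic_loop$length
      cands_d <- dfg_s[dfg_s - c_end >= cat_dfg_gap[1L] &
                       dfg_s - c_end <= cat_dfg_gap[2L]]
      if (length(cands_d)) {
        best <- c(g, cc, cands_d[1L])
        break
      }
    }
    if (!is.null(best)) break
  }

  mk <- function(motif, start) {
    if (is.null(start) || is.na(start)) NULL else match_at(chars_string(chars), motif, start)
  }
  if (!is.null(best)) {
    res <- list(gly_loop = mk(motifs$gly_loop, best[1L]),
                catalytic_loop = mk(motifs$catalytic_loop, best[2L]),
                dfg = mk(motifs$dfg, best[3L]),
                ordering_ok = TRUE)
  } else {
    first <- function(v) if (length(v)) v[1L] else NULL
    res <- list(gly_loop = mk(motifs$gly_loop, first(gly_s)),
                catalytic_loop = mk(motifs$catalytic_loop, first(cat_s)),
                dfg = mk(motifs$dfg, first(dfg_s)),
                ordering_ok = FALSE)
  }
  structure(res, class = "kinase_landmarks")
}

chars_string <- function(chars) paste0(chars, collapse = "")

#' @export
print.kinase_landmarks <- function(x, ...) {
  fmt <- function(m) if (is.null(m)) "none" else sprintf("[%d,%d)", m$start, m$end)
  cat(sprintf("<kinase_landmarks> gly_loop %s, catalytic_loop %s, dfg %s%s\n",
              fmt(x$gly_loop), fmt(x$catalytic_loop), fmt(x$dfg),
              if (x$ordering_ok) " (ordered)" else " (ordering unsatisfied)"))
  invisible(x)
}
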