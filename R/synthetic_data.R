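# Synthetic RTK protein families with planted motifs.
#
# Stands in for the transcriptome database: each sequence is assembled from a
# class-specific N-terminal cassette (for InsR, the subtype FN3 20-mer inside
# a random linker), a glycine-rich loop, a spacer, the class/subtype catalytic
# cassette (InsR: VHRDLAARNC; FGFR/PVR: the full subtype catalytic-domain
# motif, anchors included; EGFR: the artifact's synthetic context string), a
# DFG landmark where the cassette does not already contain one, and a tail.
# Wildcard positions are filled from the background distribution, point
# substitutions are applied at the stated per-position rates, and a truth
# record stores the planted label and offsets.

#' Specify a synthetic RTK family
#'
#' @param rtk_class One of `"InsR"`, `"EGFR"`, `"FGFR"`, `"PVR"`.
#' @param subtype Subtype label belonging to `rtk_class` (e.g. `"InsR3"`).
#' @param n Number of sequences.
#' @param p_fix Per-position substitution probability at fixed motif positions
#'   (planted landmarks included).
#' @param p_bg Per-position substitution probability elsewhere (linkers,
#'   spacers, wildcard fills).
#' @param background Residue sampling distribution: `NULL` for uniform over
#'   the 20 amino acids, or a named numeric vector of frequencies.
#' @param truncation `"none"`, `"n_terminal"` (N-terminal part removed) or
#'   `"c_terminal"` (C-terminal part removed).
#' @param retained Fraction of the full-length sequence retained after
#'   truncation.
#' @param nterm_len,spacer_len,tail_len Integer ranges (length 2) for the
#'   N-terminal linker, inter-cassette spacers, and C-terminal tail.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(rtk_class, subtype, n = 1L, p_fix = 0, p_bg = 0,
                           background = NULL, truncation = c("none", "n_terminal",
                                                             "c_terminal"),
                           retained = 1, nterm_len = c(200L, 400L),
                           spacer_len = c(30L, 80L), tail_len = c(30L, 60L),
                           seed = 1L) {
  truncation <- match.arg(truncation)
  rtk_class <- match.arg(rtk_class, .rtk_classes)
  if (!subtype %in% .rtk_subtypes[[rtk_class]]) {
    stop("subtype '", subtype, "' does not belong to class '", rtk_class, "'",
         call. = FALSE)
  }
  stopifnot(n >= 1L, p_fix >= 0, p_fix <= 1, p_bg >= 0, p_bg <= 1,
            retained > 0, retained <= 1)
  if (!is.null(background)) {
    stopifnot(is.numeric(background), all(names(background) %in% AA20),
              all(background >= 0), sum(background) > 0)
  }
  structure(list(rtk_class = rtk_class, subtype = subtype, n = as.integer(n),
                 p_fix = p_fix, p_bg = p_bg, background = background,
                 truncation = truncation, retained = retained,
                 nterm_len = as.integer(nterm_len),
                 spacer_len = as.integer(spacer_len),
                 tail_len = as.integer(tail_len), seed = as.integer(seed)),
            class = "synthetic_spec")
}

.sample_bg <- function(n, background) {
  if (n <= 0L) return(character(0))
  if (is.null(background)) {
    sample(AA20, n, replace = TRUE)
  } else {
    sample(names(background), n, replace = TRUE,
           prob = background / sum(background))
  }
}

# instantiate a degenerate motif: fixed positions keep their residue (first of
# a set), wildcards are drawn from the background; returns residues plus the
# fixed/universal index masks
.instantiate_motif <- function(motif, background) {
  chars <- character(motif$length)
  fixed <- logical(motif$length)
  for (j in seq_len(motif$length)) {
    p <- motif$positions[[j]]
    if (is.null(p)) {
      chars[j] <- .sample_bg(1L, background)
    } else {
      chars[j] <- p[1L]
      fixed[j] <- TRUE
    }
  }
  list(chars = chars, fixed = fixed)
}

#' Generate one synthetic RTK sequence
#'
#' @param spec A [synthetic_spec()].
#' @param index Record index within the spec (each index has its own derived
#'   seed, so records are independent yet reproducible).
#' @param library Motif library providing the cassette motifs.
#' @return List with elements `record` (a [seq_record()]) and `truth` (planted
#'   label, 0-based offsets of every planted motif, truncation bookkeeping,
#'   and `evidence_lost` flags for motifs removed by truncation).
#' @export
generate_sequence <- function(spec, index = 1L, library = load_motif_library()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(derive_seed(spec$seed, index), {
    .generate_sequence_impl(spec, index, library)
  })
}

.generate_sequence_impl <- function(spec, index, library) {
  bg <- spec$background
  rint <- function(range) if (range[1L] >= range[2L]) range[1L] else
    sample(range[1L]:range[2L], 1L)
  lm <- landmark_motifs()

  pieces <- list()       # each: list(chars, fixed, name or NA)
  add_bg <- function(n) {
    pieces[[length(pieces) + 1L]] <<- list(chars = .sample_bg(n, bg),
                                           fixed = logical(n), name = NA)
  }
  add_motif <- function(motif, tag) {
    inst <- .instantiate_motif(motif, bg)
    pieces[[length(pieces) + 1L]] <<- list(chars = inst$chars,
                                           fixed = inst$fixed, name = tag)
  }

  # --- N-terminal cassette -------------------------------------------------
  add_bg(rint(spec$nterm_len))
  if (spec$rtk_class == "InsR") {
    fn3 <- library_motifs(library, "InsR", "fn3")
    fn3 <- Filter(function(m) identical(m$subtype, spec$subtype), fn3)[[1L]]
    add_motif(fn3, "fn3")
    add_bg(rint(spec$spacer_len))
  }

  # --- kinase cassette -----------------------------------------------------
  add_motif(lm$gly_loop, "gly_loop")
  add_bg(rint(spec$spacer_len))
  cassette <- switch(spec$rtk_class,
    InsR = library_motifs(library, "InsR", "catalytic")[[1L]],
    EGFR = library_motifs(library, "EGFR", "egfr_context")[[1L]],
    FGFR = ,
    PVR  = {
      ms <- library_motifs(library, spec$rtk_class, "kinase_subtype")
      Filter(function(m) identical(m$subtype, spec$subtype), ms)[[1L]]
    })
  add_motif(cassette, "cassette")
  # catalytic cassettes of InsR and FGFR end before the activation loop; give
  # them the downstream DFG landmark (PVR/EGFR cassettes already contain one)
  if (spec$rtk_class %in% c("InsR", "FGFR")) {
    add_bg(rint(c(5L, 20L)))
    add_motif(lm$dfg, "dfg")
  }
  add_bg(rint(spec$tail_len))

  # --- assemble, record offsets -------------------------------------------
  chars <- unlist(lapply(pieces, `[[`, "chars"))
  fixed <- unlist(lapply(pieces, `[[`, "fixed"))
  offsets <- list()
  pos <- 0L
  for (p in pieces) {
    if (!is.na(p$name)) {
      offsets[[p$name]] <- c(start = pos, end = pos + length(p$chars))
    }
    pos <- pos + length(p$chars)
  }

  # --- substitutions -------------------------------------------------------
  sub_at <- function(idx, rate) {
    hit <- idx[stats::runif(length(idx)) < rate]
    for (i in hit) chars[i] <<- sample(setdiff(AA20, chars[i]), 1L)
    hit
  }
  substituted_fixed <- sub_at(which(fixed), spec$p_fix)
  sub_at(which(!fixed), spec$p_bg)

  # --- truncation ----------------------------------------------------------
  full_len <- length(chars)
  keep <- c(1L, full_len)
  if (spec$truncation != "none") {
    n_keep <- max(1L, floor(spec$retained * full_len))
    keep <- if (spec$truncation == "n_terminal") {
      c(full_len - n_keep + 1L, full_len)
    } else {
      c(1L, n_keep)
    }
    chars <- chars[keep[1L]:keep[2L]]
  }
  shift <- keep[1L] - 1L
  evidence_lost <- character(0)
  offsets <- Filter(Negate(is.null), lapply(stats::setNames(nm = names(offsets)),
    function(nm) {
      o <- offsets[[nm]]
      if (o["start"] >= shift && o["end"] <= keep[2L]) {
        o - shift
      } else {
        evidence_lost <<- c(evidence_lost, nm)
        NULL
      }
    }))

  id <- sprintf("syn%s_%s_%03d", spec$subtype, spec$seed, index)
  record <- seq_record(id, paste0(chars, collapse = ""),
                       is_partial = spec$truncation != "none")
  truth <- list(id = id, rtk_class = spec$rtk_class, subtype = spec$subtype,
                offsets = offsets, truncation = spec$truncation,
                retained = spec$retained, full_length = full_len,
                n_substituted_fixed = length(substituted_fixed),
                evidence_lost = evidence_lost)
  list(record = record, truth = truth)
}

#' Generate a labelled synthetic dataset
#'
#' @param specs A [synthetic_spec()] or list of them.
#' @param fasta,truth Optional output paths; when given, the records are
#'   written as FASTA and the truth table as TSV (1-based offsets in the
#'   offset columns).
#' @param library Motif library providing the cassette motifs.
#' @return List with `records` (list of [seq_record()]) and `truth`
#'   (data frame: `id`, `rtk_class`, `subtype`, `truncation`, `offsets` as a
#'   semicolon-joined `name:start-end` 1-based string, `evidence_lost`).
#' @export
generate_dataset <- function(specs, fasta = NULL, truth = NULL,
                             library = load_motif_library()) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  records <- list()
  rows <- list()
  for (spec in specs) {
    for (i in seq_len(spec$n)) {
      g <- generate_sequence(spec, index = i, library = library)
      records[[length(records) + 1L]] <- g$record
      tr <- g$truth
      off_str <- paste(vapply(names(tr$offsets), function(nm) {
        o <- tr$offsets[[nm]]
        sprintf("%s:%d-%d", nm, o[["start"]] + 1L, o[["end"]])  # 1-based incl.
      }, character(1)), collapse = ";")
      rows[[length(rows) + 1L]] <- data.frame(
        id = tr$id, rtk_class = tr$rtk_class, subtype = tr$subtype,
        truncation = tr$truncation, offsets = off_str,
        evidence_lost = paste(tr$evidence_lost, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in generated dataset (overlapping specs?): ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  truth_tab <- do.call(rbind, rows)
  if (!is.null(fasta)) write_fasta(records, fasta)
  if (!is.null(truth)) {
    utils::write.table(truth_tab, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(records = records, truth = truth_tab)
}

#' Generate a grouped alignment from consensus motifs
#'
#' Each group's rows copy the group consensus at fixed positions and fill
#' wildcard columns per the chosen policy.  No indels are introduced, so the
#' rows are pre-aligned.
#'
#' @param motifs Named character vector: group label -> consensus string (all
#'   the same length; `x` = wildcard).
#' @param n_per_group Rows per group.
#' @param wildcard_policy `"rotation"` cycles each wildcard column through a
#'   random residue permutation so that no residue's within-group column
#'   frequency exceeds (approximately) `max_freq`; `"background"` samples
#'   wildcards independently from the uniform background.
#' @param max_freq Frequency cap for the rotation policy (exact when
#'   `1/max_freq` divides `n_per_group`).
#' @param seed Integer seed.
#' @return A [grouped_alignment()].
#' @export
generate_grouped_alignment <- function(motifs, n_per_group = 20L,
                                       wildcard_policy = c("rotation", "background"),
                                       max_freq = 0.25, seed = 1L) {
  wildcard_policy <- match.arg(wildcard_policy)
  stopifnot(n_per_group >= 1L, max_freq > 0, max_freq <= 1)
  if (length(unique(nchar(motifs))) > 1L) {
    stop("motif strings have unequal lengths", call. = FALSE)
  }
  withr::with_seed(derive_seed(seed, 0L), {
    width <- nchar(motifs[[1L]])
    m_rot <- max(2L, ceiling(1 / max_freq))
    rows <- character(0)
    group_of <- character(0)
    for (g in names(motifs)) {
      tmpl <- strsplit(motifs[[g]], "", fixed = TRUE)[[1L]]
      wild <- which(tmpl == "x")
      rotors <- lapply(wild, function(j) sample(AA20, m_rot))
      for (i in seq_len(n_per_group)) {
        chars <- tmpl
        if (length(wild)) {
          chars[wild] <- if (wildcard_policy == "rotation") {
            vapply(seq_along(wild), function(k) {
              rotors[[k]][((i - 1L) %% m_rot) + 1L]
            }, character(1))
          } else {
            sample(AA20, length(wild), replace = TRUE)
          }
        }
        id <- sprintf("%s_%02d", g, i)
        rows[id] <- paste0(chars, collapse = "")
        group_of[id] <- g
      }
    }
    grouped_alignment(rows, group_of)
  })
}
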