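# Hierarchical class/subtype assignment.
#
# Decision procedure per sequence:
#   1. locate the shared kinase landmarks (glycine loop, catalytic loop, DFG);
#   2. class call from class-marker scores: the InsR catalytic-loop 10-mer,
#      the best FGFR and PVR subtype catalytic-domain motif, and the
#      artifact's EGFR context string.  A perfect VHRDLAARNC always wins
#      (evidence-ranked priority); EGFR is only called when the other three
#      class tests fail AND landmarks are present AND either the supplied
#      architecture matches the EGFR signature or the context string scores
#      >= theta_class.  Sequences lacking the kinase region may still be
#      called InsR from the N-terminal FN3 20-mers alone (tier "partial").
#   3. subtype call: best subtype motif with score >= theta_sub and margin to
#      the runner-up >= delta; the winning match's universal positions decide
#      the confidence tier (all intact -> "full" when landmarks are ordered).
#   4. optional domain-architecture consistency check; a conflict demotes the
#      tier to "ambiguous" and is recorded in the evidence list.

#' Classifier parameters
#'
#' @param theta_class Minimum class-marker score for a class call.
#' @param theta_sub Minimum subtype-motif score for a subtype call.
#' @param margin Minimum score margin over the runner-up subtype.
#' @param relaxed_catloop Admit the HRDLA variant of the PVR catalytic-loop
#'   anchor (the published Lv-VEGFR2 G-to-R exception).
#' @param fgfr_gap,pvr_gap Interior-length bounds for the anchored-region
#'   evidence (FGFR: VAVK..HRDLA; PVR: HGDLA..PxKW).
#' @return Named list of parameters.
#' @export
classifier_params <- function(theta_class = 0.8, theta_sub = 0.7, margin = 0.02,
                              relaxed_catloop = FALSE,
                              fgfr_gap = c(100L, 125L), pvr_gap = c(30L, 50L)) {
  stopifnot(theta_class >= 0, theta_class <= 1, theta_sub >= 0, theta_sub <= 1,
            margin >= 0)
  list(theta_class = theta_class, theta_sub = theta_sub, margin = margin,
       relaxed_catloop = isTRUE(relaxed_catloop),
       fgfr_gap = as.integer(fgfr_gap), pvr_gap = as.integer(pvr_gap))
}

# anchor pairs for the two bounded catalytic-domain motif regions
.class_anchors <- function(params) {
  vavk  <- compile_motif("VAVK", 1:4, name = "VAVK")
  hrdla <- compile_motif("HRDLA", 1:5, name = "HRDLA")
  hgdla <- if (params$relaxed_catloop) {
    compile_motif("H[GR]DLA", c(1, 3, 4, 5), name = "H[GR]DLA")
  } else {
    compile_motif("HGDLA", 1:5, name = "HGDLA")
  }
  pxkw <- compile_motif("PxKW", c(1, 3, 4), name = "PxKW")
  list(FGFR = anchor_pair(vavk, hrdla, params$fgfr_gap[1L], params$fgfr_gap[2L]),
       PVR  = anchor_pair(hgdla, pxkw, params$pvr_gap[1L], params$pvr_gap[2L]))
}

.best_of <- function(chars, motifs) {
  best <- NULL
  for (m in motifs) {
    hit <- .best_match(chars, m)
    if (!is.null(hit) && (is.null(best) || hit$score > best$score)) best <- hit
  }
  best
}

.evidence <- function(kind, detail) list(kind = kind, detail = detail)

#' Classify one sequence
#'
#' @param seq A [seq_record()] or residue string.
#' @param library A [load_motif_library()] object.
#' @param domains Optional domain annotations for this sequence (data frame as
#'   returned per-sequence by [read_domains()]).
#' @param params A [classifier_params()] list.
#' @return Object of class `classification_result`: `seq_id`, `rtk_class`
#'   (`InsR`/`EGFR`/`FGFR`/`PVR`/`unknown`), `subtype` (or `"unassigned"`),
#'   `tier` (`full`, `partial`, `architecture_only`, `ambiguous`),
#'   `best_score`, `class_scores`, `evidence` (list of findings), `landmarks`.
#' @export
classify <- function(seq, library = load_motif_library(), domains = NULL,
                     params = classifier_params()) {
  chars <- as_residues(seq)
  id <- seq_id(seq)
  evidence <- list()

  landmarks <- locate_kinase_landmarks(chars_string(chars))
  if (!is.null(landmarks$catalytic_loop)) {
    evidence <- c(evidence, list(.evidence("landmarks", sprintf(
      "gly_loop=%s catalytic_loop=%s dfg=%s ordered=%s",
      .fmt_match(landmarks$gly_loop), .fmt_match(landmarks$catalytic_loop),
      .fmt_match(landmarks$dfg), landmarks$ordering_ok))))
  }

  # --- class-marker scores -------------------------------------------------
  insr_cat <- .best_of(chars, library_motifs(library, "InsR", "catalytic"))
  fn3_best <- .best_of(chars, library_motifs(library, "InsR", "fn3"))
  fgfr_best <- .best_of(chars, library_motifs(library, "FGFR", "kinase_subtype"))
  pvr_best <- .best_of(chars, library_motifs(library, "PVR", "kinase_subtype"))
  egfr_best <- .best_of(chars, library_motifs(library, "EGFR", "egfr_context"))
  score_of <- function(m) if (is.null(m)) 0 else m$score
  class_scores <- c(InsR = max(score_of(insr_cat), score_of(fn3_best)),
                    EGFR = score_of(egfr_best),
                    FGFR = score_of(fgfr_best),
                    PVR  = score_of(pvr_best))

  anchors <- .class_anchors(params)
  fgfr_region <- find_anchored_region(chars_string(chars), anchors$FGFR)
  pvr_region  <- find_anchored_region(chars_string(chars), anchors$PVR)
  if (nrow(fgfr_region)) {
    evidence <- c(evidence, list(.evidence("anchored_region", sprintf(
      "VAVK..HRDLA at [%d,%d) interior %d", fgfr_region$start[1L],
      fgfr_region$end[1L], fgfr_region$interior[1L]))))
  }
  if (nrow(pvr_region)) {
    evidence <- c(evidence, list(.evidence("anchored_region", sprintf(
      "%s..PxKW at [%d,%d) interior %d%s",
      anchors$PVR$n_anchor$name, pvr_region$start[1L], pvr_region$end[1L],
      pvr_region$interior[1L],
      if (params$relaxed_catloop) " (relaxed catalytic-loop anchor)" else ""))))
  }

  # --- class decision ------------------------------------------------------
  th <- params$theta_class
  rtk_class <- "unknown"
  if (!is.null(insr_cat) && insr_cat$score == 1) {
    rtk_class <- "InsR"           # a perfect VHRDLAARNC always wins
  } else {
    candidates <- c("InsR", "FGFR", "PVR")
    cand_scores <- class_scores[candidates]
    cand_scores <- cand_scores[cand_scores >= th]
    if (length(cand_scores)) {
      rtk_class <- names(cand_scores)[which.max(cand_scores)]
    } else {
      # elimination route to EGFR: landmarks with canonical HRDLA, all other
      # class tests failed, plus context-string or architecture support
      canonical <- !is.null(landmarks$catalytic_loop) &&
        substr(chars_string(chars[landmarks$catalytic_loop$start + 1:5]), 2, 2) == "R"
      arch_ok <- !is.null(domains) && "EGFR" %in% architecture_class(domains)
      if (canonical && landmarks$ordering_ok &&
          (class_scores[["EGFR"]] >= th || arch_ok)) {
        rtk_class <- "EGFR"
        if (arch_ok && class_scores[["EGFR"]] < th) {
          evidence <- c(evidence,
                        list(.evidence("architecture", "EGFR signature matched")))
        }
      }
    }
  }

  marker <- switch(rtk_class, InsR = insr_cat, EGFR = egfr_best,
                   FGFR = fgfr_best, PVR = pvr_best, NULL)
  if (!is.null(marker) && rtk_class != "unknown") {
    evidence <- c(evidence, list(.evidence("class_marker", .fmt_match(marker))))
  }
  if (rtk_class == "PVR" && params$relaxed_catloop && nrow(pvr_region)) {
    region_cat <- chars_string(chars[pvr_region$start[1L] + 1:5])
    if (substr(region_cat, 2, 2) == "R") {
      evidence <- c(evidence, list(.evidence(
        "variant", "catalytic-loop G->R variant (HRDLA in place of HGDLA)")))
    }
  }

  # --- subtype decision ----------------------------------------------------
  subtype <- "unassigned"
  tier <- "ambiguous"
  best_sub <- NULL
  margin_ok <- TRUE
  if (rtk_class != "unknown") {
    sub_motifs <- switch(rtk_class,
      InsR = library_motifs(library, "InsR", "fn3"),
      EGFR = library_motifs(library, "EGFR", "egfr_context"),
      FGFR = library_motifs(library, "FGFR", "kinase_subtype"),
      PVR  = library_motifs(library, "PVR", "kinase_subtype"))
    hits <- lapply(sub_motifs, .best_match, chars = chars)
    keep <- !vapply(hits, is.null, logical(1))
    hits <- hits[keep]
    sub_motifs <- sub_motifs[keep]
    if (length(hits)) {
      scores <- vapply(hits, `[[`, numeric(1), "score")
      ord <- order(-scores)
      best_sub <- hits[[ord[1L]]]
      runner <- if (length(ord) > 1L) scores[ord[2L]] else 0
      margin_ok <- (scores[ord[1L]] - runner) >= params$margin
      if (best_sub$score >= params$theta_sub && margin_ok) {
        subtype <- sub_motifs[[ord[1L]]]$subtype
        evidence <- c(evidence,
                      list(.evidence("subtype_motif", .fmt_match(best_sub))))
      }
    }

    kinase_evidence <- landmarks$ordering_ok &&
      ((rtk_class == "InsR" && !is.null(insr_cat) && insr_cat$score >= th) ||
       rtk_class != "InsR")
    tier <- if (subtype != "unassigned") {
      if (kinase_evidence && best_sub$universal_ok) "full" else "partial"
    } else if (!margin_ok) "ambiguous" else "partial"
  }

  # --- architecture consistency -------------------------------------------
  if (!is.null(domains)) {
    compatible <- architecture_class(domains)
    if (rtk_class == "unknown") {
      if (length(compatible) == 1L) {
        rtk_class <- compatible
        tier <- "architecture_only"
        evidence <- c(evidence, list(.evidence(
          "architecture", paste0(rtk_class, " signature matched (no motif evidence)"))))
      }
    } else if (!rtk_class %in% compatible) {
      tier <- "ambiguous"
      evidence <- c(evidence, list(.evidence("architecture_conflict", sprintf(
        "motif call %s incompatible with architecture {%s}", rtk_class,
        paste(compatible, collapse = ",")))))
    } else {
      evidence <- c(evidence, list(.evidence(
        "architecture", paste0(rtk_class, " signature matched"))))
    }
  }

  structure(list(seq_id = id, rtk_class = rtk_class, subtype = subtype,
                 tier = tier,
                 best_score = if (rtk_class == "unknown") NA_real_ else
                   unname(class_scores[rtk_class]),
                 class_scores = class_scores, evidence = evidence,
                 landmarks = landmarks),
            class = "classification_result")
}

.fmt_match <- function(m) {
  if (is.null(m)) return("none")
  sprintf("%s@[%d,%d) score=%.3f%s", m$motif_name, m$start, m$end, m$score,
          if (isTRUE(m$universal_ok)) " universal_ok" else "")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s: %s / %s (tier %s, score %s)\n", x$seq_id,
              x$rtk_class, x$subtype, x$tier,
              ifelse(is.na(x$best_score), "NA", sprintf("%.3f", x$best_score))))
  invisible(x)
}

#' Classify a batch of sequences
#'
#' @param records List of [seq_record()] objects.
#' @param library,params As for [classify()].
#' @param domains Optional named list of per-sequence domain annotations (as
#'   from [read_domains()]).
#' @return List with `results` (one [classify()] result per record, input
#'   order), `table` (one row per record: `seq_id`, `class`, `subtype`,
#'   `tier`, `best_score`, `evidence`), and `summary` (counts per class /
#'   subtype / tier).
#' @export
classify_batch <- function(records, library = load_motif_library(),
                           domains = NULL, params = classifier_params()) {
  results <- lapply(records, function(r) {
    classify(r, library = library, domains = domains[[r$id]], params = params)
  })
  if (!length(results)) {
    empty <- data.frame(seq_id = character(0), class = character(0),
                        subtype = character(0), tier = character(0),
                        best_score = numeric(0), evidence = character(0))
    return(list(results = results, table = empty,
                summary = data.frame(class = character(0), subtype = character(0),
                                     tier = character(0), n = integer(0))))
  }
  tab <- do.call(rbind, lapply(results, function(x) {
    data.frame(seq_id = x$seq_id, class = x$rtk_class, subtype = x$subtype,
               tier = x$tier, best_score = x$best_score,
               evidence = paste(vapply(x$evidence, function(e) {
                 paste0(e$kind, "=", e$detail)
               }, character(1)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  summary <- stats::aggregate(list(n = seq_len(nrow(tab))),
                              by = tab[, c("class", "subtype", "tier")], length)
  summary <- summary[order(summary$class, summary$subtype, summary$tier), ]
  rownames(summary) <- NULL
  list(results = results, table = tab, summary = summary)
}

#' Confusion matrix of a batch against a truth table
#'
#' @param batch Output of [classify_batch()].
#' @param truth Truth data frame from [generate_dataset()] (`id`, `rtk_class`,
#'   `subtype`).
#' @param level `"subtype"` or `"class"`.
#' @return A contingency table `truth x called`.
#' @export
confusion_matrix <- function(batch, truth, level = c("subtype", "class")) {
  level <- match.arg(level)
  tab <- batch$table
  m <- match(tab$seq_id, truth$id)
  stopifnot(!anyNA(m))
  truth_lab <- if (level == "subtype") truth$subtype[m] else truth$rtk_class[m]
  called <- if (level == "subtype") tab$subtype else tab$class
  table(truth = truth_lab, called = called)
}

#' Compatible receptor classes for a domain architecture
#'
#' Signatures over the annotated extracellular/kinase domains:
#' \describe{
#'   \item{InsR}{two Receptor L (leucine-rich) domains, at least one furin-like
#'     cysteine-rich domain, two FN3 domains; kinase domain optional (partial
#'     contigs may lack it).}
#'   \item{EGFR}{two Receptor L domains, one or two furin-like domains, one
#'     growth-factor receptor domain IV, kinase domain.}
#'   \item{FGFR}{one to three immunoglobulin-like domains or one cadherin
#'     tandem repeat, kinase domain.}
#'   \item{PVR}{two to five immunoglobulin-like domains, kinase domain.}
#' }
#'
#' @param domains Data frame of annotations for one sequence (columns `domain`,
#'   `start`, `end`), as returned per-sequence by [read_domains()].
#' @return Character vector of compatible class labels (possibly empty).
#' @export
architecture_class <- function(domains) {
  counts <- table(factor(domains$domain, levels = .domain_vocab))
  n <- function(d) unname(counts[d])
  out <- character(0)
  if (n("RECEPTOR_L") == 2L && n("FURIN_LIKE") >= 1L && n("FN3") == 2L) {
    out <- c(out, "InsR")
  }
  if (n("RECEPTOR_L") == 2L && n("FURIN_LIKE") >= 1L && n("FURIN_LIKE") <= 2L &&
      n("GF_IV") == 1L && n("TK") >= 1L) {
    out <- c(out, "EGFR")
  }
  if (((n("IG_LIKE") >= 1L && n("IG_LIKE") <= 3L) || n("CADHERIN") == 1L) &&
      n("TK") >= 1L) {
    out <- c(out, "FGFR")
  }
  if (n("IG_LIKE") >= 2L && n("IG_LIKE") <= 5L && n("TK") >= 1L) {
    out <- c(out, "PVR")
  }
  out
}
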