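## The integrated criterion: a deterministic rule cascade mapping per-nucleus
## features (marker levels, subnuclear patterns, nuclear morphometry, cyst
## size) to one of twelve spermatogenic cell types/subtypes.

#' Default classification and localization thresholds
#'
#' All decision boundaries of the rule cascade and the pattern classifier,
#' in one editable list:
#' \describe{
#'   \item{ddx4_high / ddx4_mid / marker_absent}{relative-intensity cuts for
#'     the decreasing Ddx4 series (SPG-A above \code{ddx4_high}, SPG-B in
#'     [\code{ddx4_mid}, \code{ddx4_high})); \code{marker_absent} is the
#'     generic detectability floor.}
#'   \item{pcna_high}{relative Pcna above which a cell counts as mitotically
#'     cycling.}
#'   \item{diameter_split_spgb}{diameter (um) splitting the two SPG-B
#'     classes; 4.6 is the midpoint of the published class means 5.01 and
#'     4.14.}
#'   \item{diameter_split_spc2}{diameter (um) separating SPC-II from SPD
#'     among marker-negative cells (midpoint of 4.0 and 3.0).}
#'   \item{rho_polar, coverage_polar, coverage_whole}{pattern-classifier
#'     boundaries (polarity displacement and coverage).}
#'   \item{coverage_stripe_split}{Sycp3 stripe coverage splitting mid from
#'     late zygotene.}
#'   \item{sep_same, sep_opposite}{angular separations (degrees) calling
#'     Pcna co-polar versus complementary to Sycp3.}
#'   \item{pcna_mz_level}{relative Pcna level tiebreak between MZ and LZ.}
#'   \item{t_abs}{relative level below which a pattern is absent.}
#' }
#' @return named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(ddx4_high = 0.8, ddx4_mid = 0.35, marker_absent = 0.05,
       pcna_high = 0.5,
       diameter_split_spgb = 4.6, diameter_split_spc2 = 3.5,
       rho_polar = 0.35, coverage_polar = 0.5, coverage_whole = 0.9,
       coverage_stripe_split = 0.65,
       sep_same = 60, sep_opposite = 120,
       pcna_mz_level = 0.375, t_abs = 0.05)
}

.checkThresholds <- function(t) {
  stopifnot(t$ddx4_high > t$ddx4_mid, t$ddx4_mid > t$marker_absent,
            t$marker_absent >= 0)
  t
}

#' Classify one nucleus
#'
#' First-match rule cascade over the measured, normalized features:
#' \enumerate{
#'   \item \code{r1}: meiotic Sycp3 pattern (polar/stripe/whole) calls
#'     SPC-I; the substage comes from \code{\link{stageSpc1}}.
#'   \item \code{r2}: Ddx4 >= \code{ddx4_high} in a single (cyst size <= 1)
#'     calls SPG-A(1-cell); Pcna >= \code{pcna_high} marks it mitotic,
#'     otherwise quiescent.
#'   \item \code{r3}: Ddx4 >= \code{ddx4_high} in a cyst of 2-8 calls
#'     SPG-A(2,4,8-cell).
#'   \item \code{r4}: intermediate Ddx4 with high Pcna calls SPG-B; Sycp3
#'     dots force the late branch, otherwise diameter >=
#'     \code{diameter_split_spgb} or a visible nucleolus calls the
#'     16,32-cell branch.
#'   \item \code{r5}: Sycp3 and Pcna below \code{marker_absent} and Ddx4
#'     below \code{ddx4_mid} call the post-meiotic series, ordered by
#'     nuclear size and residual Ddx4/Piwil1: SPC-II (largest), SPD (trace
#'     germline marker), SPZ (none).
#'   \item \code{r6}: fallback to the nearest class prototype in
#'     standardized (diameter, relative DAPI) space.
#' }
#' Piwil1, when present, only corroborates (trace detection in r5); it is
#' never required, so the cascade works on the Ddx4/Sycp3/Pcna triple stain.
#'
#' @param rec one-row data.frame of normalized features (see
#'   \code{\link{measureNuclei}}); relative intensities must be filled.
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @param profiles profile set used for the r6 prototype fallback.
#' @return list with \code{label}, \code{state} (quiescent/mitotic for
#'   SPG-A(1-cell), else NA) and \code{rule_trace} (character vector).
#' @export
classifyCell <- function(rec, thresholds = defaultThresholds(),
                         profiles = makeDefaultProfiles()) {
  t <- .checkThresholds(thresholds)
  if (is.na(rec$dapi_rel))
    stopWithClass("notNormalizedError",
                  "relative intensities are not filled: run applyRelativeNormalization first")
  ddx4 <- if (is.na(rec$ddx4_rel)) 0 else rec$ddx4_rel
  piwil1 <- if (is.na(rec$piwil1_rel)) 0 else rec$piwil1_rel
  pcna <- if (is.na(rec$pcna_rel)) 0 else rec$pcna_rel
  sycp3 <- if (is.na(rec$sycp3_rel)) 0 else rec$sycp3_rel
  sPat <- if (is.na(rec$sycp3_pattern)) "absent" else rec$sycp3_pattern
  cyst <- if (is.na(rec$cyst_size)) 0L else rec$cyst_size

  ## r1: meiotic Sycp3 localization
  if (sPat %in% c("polar", "stripe", "whole")) {
    st <- stageSpc1(
      list(pattern = sPat, coverage = rec$sycp3_coverage, rho = rec$sycp3_rho),
      list(pattern = if (is.na(rec$pcna_pattern)) "absent" else rec$pcna_pattern,
           coverage = rec$pcna_coverage, level = pcna),
      angleSepDeg = rec$polar_angle_sep_deg, thresholds = t)
    return(list(label = sprintf("SPC-I(%s)", st$subtype), state = NA_character_,
                rule_trace = c("r1", st$rule)))
  }
  ## r2/r3: type A spermatogonia by highest Ddx4
  if (ddx4 >= t$ddx4_high && cyst <= 1)
    return(list(label = "SPG-A(1-cell)",
                state = if (pcna >= t$pcna_high) "mitotic" else "quiescent",
                rule_trace = "r2"))
  if (ddx4 >= t$ddx4_high && cyst >= 2 && cyst <= 8)
    return(list(label = "SPG-A(2,4,8-cell)", state = NA_character_,
                rule_trace = "r3"))
  ## r4: type B spermatogonia -- second-highest Ddx4, high Pcna
  if (ddx4 >= t$ddx4_mid && ddx4 < t$ddx4_high && pcna >= t$pcna_high) {
    if (sPat == "dots")
      return(list(label = "SPG-B(64,128,256-cell)", state = NA_character_,
                  rule_trace = c("r4", "r4-dots")))
    early <- rec$diameter_um >= t$diameter_split_spgb || rec$nucleolus_count >= 1
    return(list(label = if (early) "SPG-B(16,32-cell)" else "SPG-B(64,128,256-cell)",
                state = NA_character_,
                rule_trace = c("r4", if (early) "r4-early" else "r4-late")))
  }
  ## r5: post-meiotic series -- proliferation/meiosis markers off; needs
  ## actual marker evidence, so it is skipped when the channels are missing
  if (!is.na(rec$sycp3_rel) && !is.na(rec$pcna_rel) &&
      sycp3 < t$marker_absent && pcna < t$marker_absent && ddx4 < t$ddx4_mid) {
    if (rec$diameter_um >= t$diameter_split_spc2)
      return(list(label = "SPC-II", state = NA_character_,
                  rule_trace = c("r5", "r5-spc2")))
    if (ddx4 >= t$marker_absent || piwil1 >= t$marker_absent)
      return(list(label = "SPD", state = NA_character_,
                  rule_trace = c("r5", "r5-spd")))
    return(list(label = "SPZ", state = NA_character_,
                rule_trace = c("r5", "r5-spz")))
  }
  ## r6: nearest prototype in standardized (diameter, dapi_rel); without a
  ## Sycp3 channel the five SPC-I substages are morphometrically identical,
  ## so the call is reported at type level only ("SPC-I")
  p <- profileTable(profiles)
  z <- ((rec$diameter_um - p$diameter_mean) / pmax(p$diameter_sd, 0.1))^2 +
       ((rec$dapi_rel - p$dapi_rel_mean) / pmax(p$dapi_rel_sd, 0.1))^2
  label <- p$label[which.min(z)]
  if (is.na(rec$sycp3_rel) && grepl("^SPC-I\\(", label)) label <- "SPC-I"
  list(label = label, state = NA_character_,
       rule_trace = c("r6", sprintf("r6-%s", label)))
}

#' Classify every nucleus of a features table
#'
#' @param features normalized features of one image (one normalization
#'   region).
#' @param thresholds,profiles see \code{\link{classifyCell}}.
#' @param majorityVote when TRUE, a nucleus whose label disagrees with the
#'   majority label of its cyst -- and is the only member carrying its label
#'   -- is overridden by the cyst majority (off by default).
#' @return list with \code{calls} (data.frame: id, label, state, rule_trace)
#'   and \code{summary} (named per-label counts over the 12-type vocabulary).
#' @export
classifyScene <- function(features, thresholds = defaultThresholds(),
                          profiles = makeDefaultProfiles(),
                          majorityVote = FALSE) {
  if (!nrow(features)) {
    calls <- data.frame(id = integer(), label = character(),
                        state = character(), rule_trace = character(),
                        stringsAsFactors = FALSE)
    return(list(calls = calls,
                summary = setNames(integer(length(.CELL_LABELS)), .CELL_LABELS)))
  }
  res <- lapply(seq_len(nrow(features)), function(i)
    classifyCell(features[i, ], thresholds, profiles))
  calls <- data.frame(
    id = features$id,
    label = vapply(res, `[[`, "", "label"),
    state = vapply(res, `[[`, "", "state"),
    rule_trace = vapply(res, function(r) paste(r$rule_trace, collapse = ";"), ""),
    stringsAsFactors = FALSE)

  if (majorityVote && !all(is.na(features$cyst_id))) {
    for (cid in unique(features$cyst_id)) {
      in_cyst <- which(features$cyst_id == cid)
      if (length(in_cyst) < 3) next
      tab <- table(calls$label[in_cyst])
      top <- names(tab)[which.max(tab)]
      if (tab[top] <= length(in_cyst) / 2) next
      lonely <- in_cyst[calls$label[in_cyst] != top &
                        calls$label[in_cyst] %in% names(tab)[tab == 1]]
      if (length(lonely)) {
        calls$label[lonely] <- top
        calls$rule_trace[lonely] <- paste0(calls$rule_trace[lonely], ";majority")
      }
    }
  }
  summary <- setNames(integer(length(.CELL_LABELS)), .CELL_LABELS)
  tab <- table(calls$label)
  summary[names(tab)] <- as.integer(tab)
  list(calls = calls, summary = summary)
}

#' Match segmented nuclei to ground-truth nuclei
#'
#' Greedy nearest-centroid matching: each record is matched to the closest
#' truth nucleus within one truth nuclear radius; each truth nucleus is used
#' at most once.
#'
#' @param records measured records (needs x_um, y_um).
#' @param truth ground-truth table from \code{\link{sceneTruth}}.
#' @return data.frame with \code{id} (record id) and \code{truth_id}
#'   (matched truth id or NA).
#' @export
matchTruth <- function(records, truth) {
  if (!nrow(records))
    return(data.frame(id = integer(), truth_id = integer()))
  used <- rep(FALSE, nrow(truth))
  out <- integer(nrow(records))
  for (i in order(records$id)) {
    d <- sqrt((truth$x_um - records$x_um[i])^2 +
              (truth$y_um - records$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    out[i] <- if (length(j) && d[j] <= truth$diameter_um[j] / 2 + 1e-9)
      { used[j] <- TRUE; truth$id[j] } else NA_integer_
  }
  data.frame(id = records$id, truth_id = out)
}

#' Evaluate calls against ground truth
#'
#' @param calls calls data.frame with \code{id} and \code{label}, where
#'   \code{id} identifies the matched truth nucleus (see
#'   \code{\link{matchTruth}}).
#' @param truth truth table with \code{id} and \code{label}.
#' @return list with \code{confusion} (12 x 12 matrix, rows = truth),
#'   \code{accuracy}, \code{per_class_recall} and \code{unmatched} (counts
#'   of unmatched calls and truths).
#' @export
evaluateCalls <- function(calls, truth) {
  if (anyDuplicated(calls$id)) stop("duplicate ids in calls")
  if (anyDuplicated(truth$id)) stop("duplicate ids in truth")
  m <- merge(truth[, c("id", "label")], calls[, c("id", "label")],
             by = "id", suffixes = c("_truth", "_call"))
  conf <- table(factor(m$label_truth, levels = .CELL_LABELS),
                factor(m$label_call, levels = .CELL_LABELS))
  conf <- unclass(conf)
  acc <- if (nrow(m)) sum(diag(conf)) / nrow(m) else NA_real_
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  recall[rowSums(conf) == 0] <- NA_real_
  list(confusion = conf, accuracy = acc, per_class_recall = recall,
       unmatched = c(calls = sum(!calls$id %in% truth$id),
                     truth = sum(!truth$id %in% calls$id)))
}
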