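#' Default narrative map
#'
#' Loads the shipped YAML map of feature patterns to literature-style
#' explanatory sentences covering common PET/CT texture, intensity, shape
#' and clinical/serological feature names, plus a generic fallback. The
#' shipped sentences are original package-authored paraphrases; users
#' extend or replace the map with their own YAML via [readNarrativeMap()].
#'
#' @return list with `patterns` (list of `pattern`/`text`), `risk_labels`
#'   and `fallback`.
#' @export
defaultNarrativeMap <- function() {
  readNarrativeMap(system.file("extdata", "narrative_map.yaml",
                               package = "RiskAvatar", mustWork = TRUE))
}

#' @rdname defaultNarrativeMap
#' @param path YAML file with `patterns`, `risk_labels`, `fallback`.
#' @export
readNarrativeMap <- function(path) {
  map <- yaml::read_yaml(path)
  if (is.null(map$fallback)) stop("narrative map must define a fallback")
  map
}

fmtNum <- function(x, digits = 4) format(signif(x, digits), trim = TRUE)

renderSentence <- function(template, feature, value, attribution) {
  dir <- if (attribution >= 0) "raises" else "lowers"
  out <- gsub("{feature}", feature, template, fixed = TRUE)
  out <- gsub("{value}", fmtNum(value), out, fixed = TRUE)
  out <- gsub("{attribution}", sprintf("%+0.3f log-odds", attribution),
              out, fixed = TRUE)
  gsub("{direction}", dir, out, fixed = TRUE)
}

#' Generate a deterministic individualized clinical report
#'
#' Translates a [LocalExplanation-class] into a Markdown narrative: risk
#' category and borderline status, the top contributors each rendered via
#' the first matching narrative pattern (else the fallback, which names the
#' feature verbatim), cohort-level stump thresholds where available, and a
#' what-if summary from ICE curves. Identical inputs yield byte-identical
#' output apart from the timestamp line.
#'
#' @param explanation a [LocalExplanation-class].
#' @param rules named list of `"ThresholdRule"` (per feature), optional.
#' @param ice list of `"ICECurve"` objects, optional.
#' @param map narrative map ([defaultNarrativeMap()]).
#' @param m number of top contributors to narrate (default 5).
#' @param file optional output path (`.md`).
#' @return character vector of Markdown lines, invisibly when written.
#' @export
generateReport <- function(explanation, rules = list(), ice = list(),
                           map = defaultNarrativeMap(), m = 5L,
                           file = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (!length(map$patterns) && is.null(map$fallback))
    stop("empty narrative map")
  hiLab <- map$risk_labels$high %||% "High Risk"
  loLab <- map$risk_labels$low %||% "Low Risk"
  p <- explanation@probability
  thr <- explanation@threshold
  category <- if (p >= thr) hiLab else loLab

  lines <- c(
    sprintf("# Individualized Risk Report: %s", explanation@patientID),
    "",
    sprintf("- Predicted probability: **%.3f**", p),
    sprintf("- Decision threshold: %.3f", thr),
    sprintf("- Risk category: **%s**", category),
    sprintf("- Borderline: %s",
            if (explanation@borderline) "YES (probability near threshold)"
            else "no"),
    sprintf("- Cohort baseline (log-odds): %.3f", explanation@baseValue),
    "",
    "## Top contributors",
    "")
  top <- utils::head(explanation@contributions, m)
  for (i in seq_len(nrow(top))) {
    f <- top$feature[i]
    template <- map$fallback
    for (pt in map$patterns) {
      if (grepl(pt$pattern, f)) { template <- pt$text; break }
    }
    sentence <- renderSentence(template, f, top$value[i],
                               top$attribution[i])
    rule <- rules[[f]]
    if (!is.null(rule)) {
      side <- if (rule$direction == "above_raises_risk") "above" else "below"
      sentence <- paste0(sentence,
                         sprintf(" Cohort-level analysis places a risk inflection at %s (risk elevated %s it).",
                                 fmtNum(rule$cutoff), side))
    }
    lines <- c(lines, sprintf("%d. %s", i, sentence))
  }
  if (length(ice)) {
    lines <- c(lines, "", "## What-if analysis", "")
    for (cv in ice) {
      dp <- diff(cv$probability)
      j <- if (length(dp)) which.max(abs(dp)) else 1L
      lines <- c(lines, sprintf(
        "- Varying %s over [%s, %s] moves the predicted risk across [%.3f, %.3f]; the largest single-step shift (%+.3f) occurs near %s.",
        cv$feature, fmtNum(min(cv$grid)), fmtNum(max(cv$grid)),
        min(cv$probability), max(cv$probability),
        if (length(dp)) dp[j] else 0,
        fmtNum((cv$grid[j] + cv$grid[min(j + 1, length(cv$grid))]) / 2)))
    }
  }
  lines <- c(lines, "",
             sprintf("generated: %s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Mask the timestamp line of a generated report
#'
#' Utility for byte-level comparison of reports generated at different
#' times.
#'
#' @param lines character vector from [generateReport()].
#' @return the lines with the timestamp replaced by `generated: MASKED`.
#' @export
maskTimestamp <- function(lines) {
  sub("^generated: .*$", "generated: MASKED", lines)
}
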