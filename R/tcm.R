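# Rule-based mapping of MedDRA Preferred Terms (with their System Organ
# Class) onto Traditional Chinese Medicine functional systems.

#' Load a MedDRA-to-TCM mapping rule set
#'
#' Reads a YAML rule file with three blocks: `systems` (the functional
#' system vocabulary), `pt_rules` (exact Preferred Term -> systems) and
#' `soc_rules` (System Organ Class default -> systems). Rules targeting a
#' system outside the vocabulary are a load error. The package ships a
#' default rule set (16 systems: the five Zang organs plus the Pericardium,
#' six Fu organs, Body Surface, Chong-Ren Meridians, Meridians and
#' Collaterals, Qi-Blood-Fluid) under
#' `system.file("extdata", "tcm_rules.yaml", package = "msat")`.
#'
#' @param ruleFile path to the YAML rule file; defaults to the shipped set.
#' @return a [TcmRuleSet-class].
#' @export
loadTcmRules <- function(ruleFile = system.file("extdata", "tcm_rules.yaml",
                                                package = "msat")) {
  raw <- yaml::read_yaml(ruleFile)
  systems <- as.character(raw$systems %||% character(0))
  pt <- lapply(raw$pt_rules %||% list(), as.character)
  soc <- lapply(raw$soc_rules %||% list(), as.character)
  if (length(systems) == 0 && length(pt) == 0 && length(soc) == 0) {
    warning("empty rule file: every term will map as unmapped", call. = FALSE)
  }
  methods::new("TcmRuleSet", systems = systems, ptRules = pt, socRules = soc)
}

setMethod("show", "TcmRuleSet", function(object) {
  cat(sprintf(
    "TcmRuleSet: %d functional systems, %d PT rule(s), %d SOC default(s)\n",
    length(object@systems), length(object@ptRules), length(object@socRules)
  ))
  invisible(NULL)
})

#' Map one MedDRA term to TCM functional systems
#'
#' Dual-input first-match logic: an exact Preferred Term rule wins over the
#' SOC default (so e.g. "Jaundice" inside the Gastrointestinal disorders
#' SOC maps to the Liver system while "Nausea" falls through to the
#' Spleen/Stomach SOC default or its own PT rule); a term matched by
#' neither returns the unmapped marker (`character(0)` with attribute
#' `unmapped = TRUE`).
#'
#' @param pt Preferred Term string.
#' @param soc System Organ Class string.
#' @param rules a [TcmRuleSet-class].
#' @return character vector of functional systems (possibly empty).
#' @export
mapTerm <- function(pt, soc, rules) {
  hit <- rules@ptRules[[pt]]
  if (is.null(hit)) hit <- rules@socRules[[soc]]
  if (is.null(hit)) {
    out <- character(0)
    attr(out, "unmapped") <- TRUE
    return(out)
  }
  hit
}

#' Annotate a prediction table with TCM functional systems
#'
#' Adds a `tcm_systems` column (systems joined with `"+"`) and an
#' `unmapped` flag to a prediction table. Predictions whose ADR lacks a
#' PT -> SOC entry, or that no rule matches, are flagged and kept, never
#' dropped.
#'
#' @param predictions `data.frame` with an `adr_id` column holding MedDRA
#'   Preferred Terms.
#' @param rules a [TcmRuleSet-class].
#' @param ptToSoc `data.frame` with columns `pt`, `soc`.
#' @return `predictions` with added `soc`, `tcm_systems`, `unmapped`
#'   columns.
#' @export
mapPredictions <- function(predictions, rules, ptToSoc) {
  if (nrow(predictions) == 0) {
    predictions$soc <- character(0)
    predictions$tcm_systems <- character(0)
    predictions$unmapped <- logical(0)
    return(predictions)
  }
  soc <- ptToSoc$soc[match(predictions$adr_id, ptToSoc$pt)]
  miss <- is.na(soc)
  if (any(miss)) {
    warning(sprintf(
      "%d prediction(s) lack a PT->SOC entry and are flagged unmapped",
      sum(miss)
    ), call. = FALSE)
  }
  systems <- character(nrow(predictions))
  unmapped <- logical(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    if (miss[i]) {
      # no SOC: an exact PT rule can still apply
      hit <- rules@ptRules[[as.character(predictions$adr_id[i])]]
      if (is.null(hit)) {
        unmapped[i] <- TRUE
        next
      }
      systems[i] <- paste(hit, collapse = "+")
      next
    }
    m <- mapTerm(as.character(predictions$adr_id[i]), soc[i], rules)
    if (length(m) == 0) {
      unmapped[i] <- TRUE
    } else {
      systems[i] <- paste(m, collapse = "+")
    }
  }
  predictions$soc <- soc
  predictions$tcm_systems <- systems
  predictions$unmapped <- unmapped
  predictions
}

#' Read a PT -> SOC table
#'
#' @param path TSV with columns `pt`, `soc`. The package ships a table
#'   covering the Preferred Terms of the worked examples under
#'   `system.file("extdata", "pt_soc.tsv", package = "msat")`.
#' @return `data.frame` with columns `pt`, `soc`.
#' @export
readPtSocTable <- function(path = system.file("extdata", "pt_soc.tsv",
                                              package = "msat")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("pt", "soc") %in% names(df)), "PT->SOC table needs columns pt, soc")
  df
}
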