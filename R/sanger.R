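#' Concordance policy for Sanger validation
#'
#' @param tol Tolerance in bp for length and breakpoint agreement
#'   (default 10).
#' @param ins_max_resolvable Insertions longer than this (bp) cannot be
#'   resolved by a single Sanger reaction and are classified as uncertain
#'   (default 500).
#' @param either_breakpoint For deletions, accept agreement of either
#'   endpoint within `tol` (default `FALSE`: start coordinate only).
#' @return An object of class `concordance_policy`.
#' @export
concordance_policy <- function(tol = 10, ins_max_resolvable = 500,
                               either_breakpoint = FALSE) {
  stopifnot(tol >= 0, ins_max_resolvable > 0)
  structure(list(tol = tol, ins_max_resolvable = ins_max_resolvable,
                 either_breakpoint = either_breakpoint),
            class = "concordance_policy")
}

#' Read a table of Sanger-derived observations
#'
#' Expected TSV columns: `sv_id`, `amplified`, `sequenced`,
#' `observed_type` (`DEL`/`INS`/`none`), `observed_len`,
#' `observed_breakpoint`, `region_class` (`genic`/`intergenic`). Missing
#' observations are encoded as `NA` (or `.`).
#'
#' @param path Path to the TSV (with header line).
#' @return A tibble.
#' @export
read_sanger_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "."),
                          stringsAsFactors = FALSE)
  df <- tibble::as_tibble(df)
  df$amplified <- as.logical(df$amplified)
  df$sequenced <- as.logical(df$sequenced)
  if (any(df$sequenced & !df$amplified)) {
    stop("sequenced implies amplified; offending sv_id(s): ",
         paste(utils::head(df$sv_id[df$sequenced & !df$amplified], 5),
               collapse = ", "))
  }
  df
}

#' Classify Sanger/call concordance per validated site
#'
#' For every sequenced Sanger call, three dimensions are scored against the
#' targeted high-confidence SV: type (`observed_type == svtype`), length
#' (`|observed_len - svlen| <= tol`), breakpoint
#' (`|observed_breakpoint - start| <= tol`; 0-based, as everywhere in
#' svbench). A dimension is `uncertain` when its observation is absent, and
#' all dimensions are `uncertain` for insertions longer than
#' `ins_max_resolvable` (unresolvable in a single Sanger reaction).
#'
#' @param calls Tibble of Sanger observations (see [read_sanger_tsv()]).
#' @param svs SV tibble containing the targeted calls (matched by `sv_id`
#'   against `id`).
#' @param policy A [concordance_policy()].
#' @return Tibble with one row per sequenced call: `sv_id`, `region_class`,
#'   and `type`, `length`, `breakpoint`, each in
#'   `{"match", "mismatch", "uncertain"}`.
#' @export
classify_concordance <- function(calls, svs, policy = concordance_policy()) {
  seqd <- calls[calls$sequenced, , drop = FALSE]
  idx <- match(seqd$sv_id, svs$id)
  if (anyNA(idx)) {
    stop("Sanger call(s) target unknown SV id(s): ",
         paste(utils::head(seqd$sv_id[is.na(idx)], 5), collapse = ", "))
  }
  sv <- svs[idx, , drop = FALSE]

  score <- function(obs_ok, observed_present) {
    dplyr::case_when(
      !observed_present ~ "uncertain",
      obs_ok ~ "match",
      TRUE ~ "mismatch"
    )
  }
  has_type <- !is.na(seqd$observed_type) & seqd$observed_type != "none"
  type <- score(has_type & seqd$observed_type == sv$svtype, has_type)
  len <- score(!is.na(seqd$observed_len) &
                 abs(seqd$observed_len - sv$svlen) <= policy$tol,
               !is.na(seqd$observed_len))
  bp_start_ok <- abs(seqd$observed_breakpoint - sv$start) <= policy$tol
  bp_ok <- if (policy$either_breakpoint) {
    bp_start_ok | (sv$svtype == "DEL" &
                     abs(seqd$observed_breakpoint - sv$end) <= policy$tol)
  } else {
    bp_start_ok
  }
  brk <- score(!is.na(seqd$observed_breakpoint) & bp_ok,
               !is.na(seqd$observed_breakpoint))

  unresolvable <- sv$svtype == "INS" & sv$svlen > policy$ins_max_resolvable
  type[unresolvable] <- "uncertain"
  len[unresolvable] <- "uncertain"
  brk[unresolvable] <- "uncertain"

  tibble::tibble(
    sv_id = seqd$sv_id,
    region_class = if ("region_class" %in% names(seqd)) seqd$region_class else NA,
    type = type, length = len, breakpoint = brk
  )
}

#' Aggregate Sanger validation rates
#'
#' Computes, overall and per stratum: the amplification rate
#' (`amplified / assessed`), the sequencing rate (`sequenced / amplified`)
#' and, for each concordance dimension, the concordance rate
#' (`matches / (matches + mismatches)`, uncertain sites excluded). All
#' counts are carried alongside the rates.
#'
#' @param calls Tibble of Sanger observations (all assessed sites).
#' @param results Concordance table from [classify_concordance()] (one row
#'   per sequenced call); may be `NULL` if nothing was sequenced.
#' @param strata Character vector of stratifier columns of `calls`
#'   (default `"region_class"`).
#' @return A list with tibbles `rates` (columns `stratum`, `level`,
#'   `n_assessed`, `n_amplified`, `n_sequenced`, `amplification_rate`,
#'   `sequencing_rate`) and `concordance` (columns `stratum`, `level`,
#'   `dimension`, `n_match`, `n_mismatch`, `n_uncertain`, `rate`).
#' @export
aggregate_rates <- function(calls, results = NULL, strata = "region_class") {
  one_stratum <- function(stratum, level, sub_calls, sub_res) {
    n_assessed <- nrow(sub_calls)
    n_amp <- sum(sub_calls$amplified)
    n_seq <- sum(sub_calls$sequenced)
    rates <- tibble::tibble(
      stratum = stratum, level = level,
      n_assessed = n_assessed, n_amplified = n_amp, n_sequenced = n_seq,
      amplification_rate = ifelse(n_assessed == 0, NA_real_, n_amp / n_assessed),
      sequencing_rate = ifelse(n_amp == 0, NA_real_, n_seq / n_amp)
    )
    conc <- purrr::map_dfr(c("type", "length", "breakpoint"), function(dim) {
      v <- if (is.null(sub_res)) character() else sub_res[[dim]]
      n_match <- sum(v == "match")
      n_mismatch <- sum(v == "mismatch")
      tibble::tibble(
        stratum = stratum, level = level, dimension = dim,
        n_match = n_match, n_mismatch = n_mismatch,
        n_uncertain = sum(v == "uncertain"),
        rate = ifelse(n_match + n_mismatch == 0, NA_real_,
                      n_match / (n_match + n_mismatch))
      )
    })
    list(rates = rates, concordance = conc)
  }

  parts <- list(one_stratum("overall", "overall", calls, results))
  for (s in intersect(strata, names(calls))) {
    for (lev in sort(unique(calls[[s]]))) {
      sub_calls <- calls[calls[[s]] == lev, , drop = FALSE]
      sub_res <- if (is.null(results)) NULL else {
        results[results$sv_id %in% sub_calls$sv_id, , drop = FALSE]
      }
      parts <- c(parts, list(one_stratum(s, lev, sub_calls, sub_res)))
    }
  }
  list(rates = purrr::map_dfr(parts, "rates"),
       concordance = purrr::map_dfr(parts, "concordance"))
}
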