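#' Construct or validate a structural-variant call table
#'
#' The central data structure of svbench is a plain tibble with one row per
#' insertion or deletion call. All svbench functions accept and return this
#' shape, so results chain naturally with dplyr verbs and the pipe.
#'
#' Columns:
#' \describe{
#'   \item{id}{character, unique call identifier}
#'   \item{chrom}{character, chromosome name}
#'   \item{start}{numeric, 0-based breakpoint position}
#'   \item{end}{numeric, 0-based exclusive end of a deletion span; equals
#'     `start` for insertions}
#'   \item{svtype}{character, `"DEL"` or `"INS"`}
#'   \item{svlen}{numeric, SV length in bp (always positive)}
#'   \item{alt_seq}{character, inserted sequence for INS (`""` if unknown)}
#'   \item{ref_seq}{character, deleted sequence for DEL (`""` if unknown)}
#'   \item{support}{character, comma-joined platform labels (`""` if none)}
#'   \item{hap_support}{character, comma-joined haplotype labels out of
#'     `"paternal"`/`"maternal"` (`""` if none)}
#'   \item{genotype}{character, `"het"`, `"hom"` or `"unknown"`}
#' }
#'
#' Internally all coordinates are 0-based half-open, matching BED; VCF I/O
#' converts to and from 1-based positions at the boundary.
#'
#' @param df A data frame carrying at least `chrom`, `start`, `svtype`,
#'   `svlen`. Missing optional columns are filled with defaults.
#' @param label Optional platform label; when given and `support` is absent,
#'   every record's support is initialised to this label.
#'
#' @return A tibble sorted by `(chrom, start, end)` with the full column set.
#' @export
#' @examples
#' as_sv_tbl(data.frame(chrom = "chr1", start = 1000, svtype = "DEL", svlen = 500))
as_sv_tbl <- function(df, label = NULL) {
  df <- tibble::as_tibble(df)
  required <- c("chrom", "start", "svtype", "svlen")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("SV table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  if (!"id" %in% names(df)) df$id <- if (n) paste0("sv", seq_len(n)) else character()
  if (!"alt_seq" %in% names(df)) df$alt_seq <- rep("", n)
  if (!"ref_seq" %in% names(df)) df$ref_seq <- rep("", n)
  if (!"support" %in% names(df)) {
    df$support <- rep(if (is.null(label)) "" else label, n)
  }
  if (!"hap_support" %in% names(df)) df$hap_support <- rep("", n)
  if (!"genotype" %in% names(df)) df$genotype <- rep("unknown", n)
  df$alt_seq[is.na(df$alt_seq)] <- ""
  df$ref_seq[is.na(df$ref_seq)] <- ""
  if (!"end" %in% names(df)) {
    df$end <- ifelse(df$svtype == "DEL", df$start + df$svlen, df$start)
  }

  bad_type <- !df$svtype %in% c("DEL", "INS")
  if (any(bad_type)) {
    stop("svtype must be 'DEL' or 'INS'; offending id(s): ",
         paste(utils::head(df$id[bad_type], 5), collapse = ", "))
  }
  if (any(df$svlen < 1)) stop("svlen must be >= 1")
  del <- df$svtype == "DEL"
  if (any(del & df$end - df$start != df$svlen)) {
    stop("for DEL records end - start must equal svlen")
  }
  if (any(!del & df$end != df$start)) {
    stop("for INS records end must equal start")
  }
  if (!all(df$genotype %in% c("het", "hom", "unknown"))) {
    stop("genotype must be one of 'het', 'hom', 'unknown'")
  }

  cols <- c("id", "chrom", "start", "end", "svtype", "svlen",
            "alt_seq", "ref_seq", "support", "hap_support", "genotype")
  out <- df[, c(cols, setdiff(names(df), cols))]
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out$svlen <- as.numeric(out$svlen)
  sort_sv_tbl(out)
}

#' Sort an SV table by genomic position
#' @param svs An SV tibble (see [as_sv_tbl()]).
#' @return The same tibble ordered by `(chrom, start, end, id)`.
#' @export
sort_sv_tbl <- function(svs) {
  svs[order(svs$chrom, svs$start, svs$end, svs$id), , drop = FALSE]
}

#' Empty SV table with the canonical column set
#' @return A zero-row SV tibble.
#' @export
empty_sv_tbl <- function() {
  tibble::tibble(
    id = character(), chrom = character(), start = numeric(), end = numeric(),
    svtype = character(), svlen = numeric(), alt_seq = character(),
    ref_seq = character(), support = character(), hap_support = character(),
    genotype = character()
  )
}

# split "CCS,ONT" -> list(c("CCS","ONT")); "" -> character(0)
support_list <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE), function(v) v[nzchar(v)])
}

support_join <- function(lst) {
  unname(vapply(lst, function(v) paste(sort(unique(v)), collapse = ","),
                character(1)))
}

#' Test platform membership of the support field
#'
#' @param support Character vector of comma-joined platform labels.
#' @param label Single platform label.
#' @return Logical vector: does each record's support contain `label`?
#' @export
support_has <- function(support, label) {
  vapply(support_list(support), function(v) label %in% v, logical(1))
}

# count of labels in each record's support
support_size <- function(support) {
  lengths(support_list(support))
}
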