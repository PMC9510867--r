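#' Read an SV VCF into an SV table
#'
#' Understands the common SV dialects: `SVTYPE`/`SVLEN` INFO keys, symbolic
#' ALT alleles (`<DEL>`, `<INS>`), `END` for deletions, and base-resolved
#' REF/ALT alleles with a leading padding base. Only DEL and INS records are
#' kept; records of other SV types are skipped and counted (see the
#' `skipped` attribute of the result). Negative `SVLEN` (the deletion
#' convention of several callers) is stored as a positive length.
#'
#' Genotypes, when a GT field is present for the first sample, are collapsed
#' to `het` (one alternate allele), `hom` (two) or `unknown`.
#'
#' @param path Path to a VCF 4.x file.
#' @param label Optional platform label recorded as the `support` of every
#'   record (e.g. `"CCS"`, `"ONT"`).
#' @return An SV tibble (see [as_sv_tbl()]), 0-based coordinates, sorted.
#'   Attribute `skipped` holds the number of non-DEL/INS records dropped.
#' @export
read_sv_vcf <- function(path, label = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    out <- empty_sv_tbl()
    attr(out, "skipped") <- 0L
    attr(out, "label") <- label
    return(out)
  }

  info_get <- function(key) unname(vcfR::extract.info(vcf, element = key))
  svtype <- info_get("SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_get("SVLEN")))
  endinfo <- suppressWarnings(as.numeric(info_get("END")))
  supp <- info_get("SUPP")
  hap <- info_get("HAP")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  pos <- as.numeric(fix[, "POS"])

  # SVTYPE may be absent when symbolic ALT carries the type
  sym <- stringr::str_match(alt, "^<(DEL|INS)>$")[, 2]
  svtype <- ifelse(is.na(svtype) & !is.na(sym), sym, svtype)
  # infer from allele lengths when neither is present
  allelic <- is.na(svtype) & !is.na(alt) & !grepl("[<\\[\\]]", alt)
  svtype[allelic & nchar(alt[allelic]) > nchar(ref[allelic])] <- "INS"
  svtype[allelic & nchar(alt[allelic]) < nchar(ref[allelic])] <- "DEL"

  keep <- !is.na(svtype) & svtype %in% c("DEL", "INS")
  skipped <- sum(!keep)
  if (!any(keep)) {
    out <- empty_sv_tbl()
    attr(out, "skipped") <- skipped
    attr(out, "label") <- label
    return(out)
  }

  fix <- fix[keep, , drop = FALSE]
  svtype <- svtype[keep]; svlen <- abs(svlen[keep]); endinfo <- endinfo[keep]
  supp <- supp[keep]; hap <- hap[keep]
  ref <- ref[keep]; alt <- alt[keep]; pos <- pos[keep]
  n <- length(pos)

  symbolic <- grepl("^<", alt) | is.na(alt)
  # base-resolved alleles: strip the shared padding base if present
  alt_seq <- rep("", n)
  ref_seq <- rep("", n)
  ins <- svtype == "INS" & !symbolic
  del <- svtype == "DEL" & !symbolic
  alt_seq[ins] <- ifelse(nchar(ref[ins]) == 1,
                         substring(alt[ins], 2), alt[ins])
  ref_seq[del] <- ifelse(nchar(alt[del]) == 1,
                         substring(ref[del], 2), ref[del])
  inferred_len <- rep(NA_real_, n)
  inferred_len[ins] <- nchar(alt_seq[ins])
  inferred_len[del] <- ifelse(ref_seq[del] == "", NA_real_, nchar(ref_seq[del]))
  inferred_len[svtype == "DEL" & !is.na(endinfo)] <-
    endinfo[svtype == "DEL" & !is.na(endinfo)] - (pos[svtype == "DEL" & !is.na(endinfo)] - 1)
  svlen <- ifelse(is.na(svlen), inferred_len, svlen)
  if (anyNA(svlen)) {
    bad <- which(is.na(svlen))[1]
    stop("record ", fix[bad, "ID"], " at ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         " has no resolvable SVLEN")
  }

  start <- pos - 1
  end <- ifelse(svtype == "DEL", start + svlen, start)

  # END/SVLEN consistency: collect record-level errors, drop those records
  end_bad <- svtype == "DEL" & !is.na(endinfo) & abs(endinfo - end) > 0
  if (any(end_bad)) {
    warning(sum(end_bad), " record(s) with inconsistent END/SVLEN dropped: ",
            paste(utils::head(fix[end_bad, "ID"], 5), collapse = ", "))
  }

  gt <- rep("unknown", n)
  if (ncol(vcf@gt %||% matrix(nrow = 0, ncol = 0)) >= 2) {
    gtcol <- vcf@gt[keep, 2]
    gtfield <- sub(":.*$", "", gtcol)
    nalt <- stringr::str_count(gtfield, "1")
    gt[!is.na(nalt) & nalt == 1] <- "het"
    gt[!is.na(nalt) & nalt >= 2] <- "hom"
  }

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    if (is.null(label)) "sv" else label, "_", which(is.na(ids) | ids == "."))
  out <- as_sv_tbl(tibble::tibble(
    id = ids,
    chrom = fix[, "CHROM"],
    start = start, end = end, svtype = svtype, svlen = svlen,
    alt_seq = alt_seq, ref_seq = ref_seq,
    support = dplyr::coalesce(supp, if (is.null(label)) "" else label),
    hap_support = dplyr::coalesce(hap, ""),
    genotype = gt
  )[!end_bad, , drop = FALSE])
  attr(out, "skipped") <- skipped
  attr(out, "label") <- label
  out
}

#' Write an SV table as VCF 4.2
#'
#' Records carry `SVTYPE`, `SVLEN`, `END`, and, when non-empty, `SUPP`
#' (comma-joined platform labels) and `HAP` (haplotype labels) INFO keys,
#' plus a single-sample GT column encoding the genotype. Reading the file
#' back with [read_sv_vcf()] reproduces coordinates, types, lengths,
#' sequences, support and genotype.
#'
#' @param svs An SV tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sv_vcf <- function(svs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svbench",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive) of deletion\">",
    "##INFO=<ID=SUPP,Number=.,Type=String,Description=\"Supporting platform labels\">",
    "##INFO=<ID=HAP,Number=.,Type=String,Description=\"Supporting haplotype assemblies\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(svs) == 0) return(invisible(path))

  svs <- sort_sv_tbl(svs)
  ins <- svs$svtype == "INS"
  ref <- ifelse(ins, "N", ifelse(svs$ref_seq == "", "N", paste0("N", svs$ref_seq)))
  alt <- ifelse(ins,
                ifelse(svs$alt_seq == "", "<INS>", paste0("N", svs$alt_seq)),
                ifelse(svs$ref_seq == "", "<DEL>", "N"))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d",
                  svs$svtype,
                  as.integer(ifelse(ins, svs$svlen, -svs$svlen)),
                  as.integer(svs$end))
  info <- paste0(info, ifelse(svs$support == "", "", paste0(";SUPP=", svs$support)))
  info <- paste0(info, ifelse(svs$hap_support == "", "", paste0(";HAP=", svs$hap_support)))
  gt <- c(het = "0/1", hom = "1/1", unknown = "./.")[svs$genotype]
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                   svs$chrom, as.integer(svs$start + 1), svs$id,
                   ref, alt, info, gt)
  writeLines(lines, con)
  invisible(path)
}
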