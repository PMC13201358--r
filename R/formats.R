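# Readers and writers for the external formats the pipeline touches, plus
# the allele-harmonization rules every signed-LD computation relies on.
# All text writers are gzip-transparent (paths ending in .gz).

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Recombination map container
#'
#' Positions are 1-based bp; `rate` (cM/Mb) applies from each position to the
#' next (HapMap convention), so the cumulative map in cM is piecewise linear
#' and the rate is its derivative.
#'
#' @param positions strictly increasing 1-based positions.
#' @param rate non-negative rates in cM/Mb, one per position (the last is
#'   unused for accumulation but kept for the HapMap layout).
#' @param cumulative optional precomputed map values in cM; recomputed from
#'   `rate` when omitted.
#' @return object of class `recombination_map` (a data.frame with columns
#'   `pos`, `rate`, `map`).
#' @export
recombination_map <- function(positions, rate, cumulative = NULL) {
  if (length(positions) < 2) stop2("a map needs at least two positions")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop2("positions must be strictly increasing")
  }
  if (any(rate < 0) || any(!is.finite(rate))) stop2("rates must be finite and >= 0")
  if (length(rate) != length(positions)) stop2("rate must match positions")
  if (is.null(cumulative)) {
    dpos <- diff(positions) / 1e6
    cumulative <- c(0, cumsum(rate[-length(rate)] * dpos))
  }
  if (is.unsorted(cumulative)) stop2("cumulative map must be non-decreasing")
  structure(data.frame(pos = positions, rate = rate, map = cumulative),
            class = c("recombination_map", "data.frame"))
}

#' Write / read a recombination map (HapMap three-column format)
#'
#' @param map a [recombination_map()].
#' @param path output file (`.gz` for gzip).
#' @return `read_recomb_map` returns a [recombination_map()].
#' @export
write_recomb_map <- function(map, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines("position\trate_cM_Mb\tmap_cM", con)
  utils::write.table(data.frame(map$pos, map$rate, map$map), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(d) != 3) stop2("expected three columns (position, rate, map)")
  recombination_map(d[[1]], d[[2]], d[[3]])
}

#' Write / read GWAS summary statistics (TSV dialect)
#'
#' Columns: `CHR, POS, ID, A1, A2, BETA, SE, P, AF, N`, where `A1` is the
#' effect allele.
#'
#' @param sumstats a `summary_stats` data.frame.
#' @param path output file (`.gz` for gzip).
#' @return `read_sumstats` returns a `summary_stats` data.frame.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(CHR = sumstats$chrom, POS = sumstats$pos, ID = sumstats$id,
                    A1 = sumstats$a1, A2 = sumstats$a2, BETA = sumstats$beta,
                    SE = sumstats$se, P = sumstats$p, AF = sumstats$af,
                    N = sumstats$n)
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(CHR = "character", ID = "character",
                                        A1 = "character", A2 = "character"))
  out <- data.frame(chrom = d$CHR, pos = d$POS, id = d$ID, a1 = d$A1, a2 = d$A2,
                    beta = d$BETA, se = d$SE, p = d$P, af = d$AF, n = d$N)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read PRS weights (TSV)
#'
#' Columns `CHR, POS, ID, EFFECT_ALLELE, WEIGHT`; the clumping parameters
#' that produced the weights travel as `#key=value` header comments.
#'
#' @param weights a `prs_weights` object.
#' @param path output file (`.gz` for gzip).
#' @return `read_weights` returns a `prs_weights` object.
#' @export
write_weights <- function(weights, path) {
  con <- open_out(path)
  on.exit(close(con))
  params <- attr(weights, "params")
  if (!is.null(params)) {
    writeLines(sprintf("#%s=%s", names(params), unlist(params)), con)
  }
  sp <- attr(weights, "source_population")
  if (!is.null(sp)) writeLines(paste0("#source_population=", sp), con)
  out <- data.frame(CHR = weights$chrom, POS = weights$pos, ID = weights$id,
                    EFFECT_ALLELE = weights$effect_allele, WEIGHT = weights$weight)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         colClasses = c(CHR = "character", ID = "character",
                                        EFFECT_ALLELE = "character"))
  w <- data.frame(chrom = d$CHR, pos = d$POS, id = d$ID,
                  effect_allele = d$EFFECT_ALLELE, weight = d$WEIGHT)
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  params <- as.list(vals[keys != "source_population"])
  names(params) <- keys[keys != "source_population"]
  params <- lapply(params, function(v) {
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  prs_weights(w, params = params,
              source_population = if (any(keys == "source_population"))
                vals[keys == "source_population"][1] else NULL)
}

#' Write / read a dosage matrix (TSV)
#'
#' Layout: `CHROM POS ID A1 A2` followed by one column per sample.
#'
#' @param panel a [genotype_panel()].
#' @param path output file (`.gz` for gzip).
#' @return `read_dosage_tsv` returns a [genotype_panel()] (sample metadata
#'   beyond ids is not stored in this format).
#' @export
write_dosage_tsv <- function(panel, path) {
  out <- cbind(panel$variants[, c("chrom", "pos", "id", "a1", "a2")],
               as.data.frame(t(panel$dosage)))
  names(out) <- c("CHROM", "POS", "ID", "A1", "A2", panel$samples$sample_id)
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = c(CHROM = "character", ID = "character",
                                        A1 = "character", A2 = "character"))
  meta <- d[, 1:5]
  dos <- t(as.matrix(d[, -(1:5), drop = FALSE]))
  variants <- data.frame(chrom = meta$CHROM, pos = meta$POS, id = meta$ID,
                         a1 = meta$A1, a2 = meta$A2)
  samples <- data.frame(sample_id = rownames(dos))
  genotype_panel(dos, variants, samples)
}

#' Write a genotype panel as VCF 4.2 (GT and DS fields)
#'
#' The effect allele (`a1`) is written as ALT and `a2` as REF, so the DS
#' field carries the effect-allele dosage directly.
#'
#' @param panel a [genotype_panel()].
#' @param path output file (`.gz` for gzip; plain bgzip is not produced).
#' @export
write_vcf <- function(panel, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  ), con)
  dos <- panel$dosage
  gt <- matrix("./.", nrow(dos), ncol(dos))
  gt[!is.na(dos) & dos == 0] <- "0/0"
  gt[!is.na(dos) & dos == 1] <- "0/1"
  gt[!is.na(dos) & dos == 2] <- "1/1"
  ds <- formatC(dos, format = "g")
  ds[is.na(dos)] <- "."
  field <- matrix(paste(gt, ds, sep = ":"), nrow(dos), ncol(dos))
  v <- panel$variants
  lines <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$a2[j], v$a1[j], ".", "PASS", ".",
            "GT:DS", field[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF parsing is delegated to \pkg{vcfR}; the DS field is used when present
#' and genotypes are summed otherwise. Multi-allelic records are rejected and
#' duplicate variant keys deduplicated, both with logged counts (attributes
#' `n_multiallelic`, `n_duplicate`).
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage"`; guessed from the filename by default.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "dosage") return(read_dosage_tsv(path))
  if (file.size(path) == 0) stop2("empty file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stop2("no records parsed from ", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  key <- variant_key(fix$CHROM, fix$POS)
  dup <- duplicated(key)
  keep <- !multi & !dup
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(ds))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(vapply(gsub("\\|", "/", gt), function(g) {
      if (is.na(g) || g == "./.") return(NA_real_)
      sum(as.numeric(strsplit(g, "/")[[1]]))
    }, numeric(1)), nrow(gt), ncol(gt))
    dimnames(ds) <- dimnames(gt)
  }
  dos <- t(ds[keep, , drop = FALSE])
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         id = fix$ID[keep],
                         a1 = fix$ALT[keep], a2 = fix$REF[keep])
  panel <- genotype_panel(dos, variants,
                          data.frame(sample_id = rownames(dos)))
  attr(panel, "n_multiallelic") <- sum(multi)
  attr(panel, "n_duplicate") <- sum(dup & !multi)
  panel
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a genotype panel's allele orientation
#'
#' Restricts to the variant intersection (by chromosome and position). Where
#' the panel's effect/other alleles are swapped relative to the summary
#' statistics, the effect size is negated and the frequency complemented.
#' Strand-ambiguous (A/T, C/G) variants and allele-mismatched records are
#' dropped. Drop counts are logged as attributes (`n_ambiguous`,
#' `n_unmatched`, `n_mismatched`, `n_flipped`). The operation is idempotent.
#'
#' @param sumstats a `summary_stats` data.frame.
#' @param panel a [genotype_panel()].
#' @return harmonized `summary_stats` restricted to the intersection, in
#'   panel allele orientation.
#' @export
harmonize <- function(sumstats, panel) {
  amb <- strand_ambiguous(sumstats$a1, sumstats$a2)
  ss <- sumstats[!amb, , drop = FALSE]
  pkey <- variant_key(panel$variants$chrom, panel$variants$pos)
  skey <- variant_key(ss$chrom, ss$pos)
  idx <- match(skey, pkey)
  matched <- !is.na(idx)
  ss <- ss[matched, , drop = FALSE]
  pv <- panel$variants[idx[matched], , drop = FALSE]
  aligned <- ss$a1 == pv$a1 & ss$a2 == pv$a2
  swapped <- ss$a1 == pv$a2 & ss$a2 == pv$a1
  keep <- aligned | swapped
  out <- ss[keep, , drop = FALSE]
  sw <- swapped[keep]
  out$beta[sw] <- -out$beta[sw]
  out$af[sw] <- 1 - out$af[sw]
  tmp <- out$a1[sw]
  out$a1[sw] <- out$a2[sw]
  out$a2[sw] <- tmp
  if (nrow(out) == 0) stop2("no overlapping variants after harmonization")
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "n_ambiguous") <- sum(amb)
  attr(out, "n_unmatched") <- sum(!matched)
  attr(out, "n_mismatched") <- sum(!keep)
  attr(out, "n_flipped") <- sum(sw)
  out
}
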