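#' Genotype panel container
#'
#' A genotype panel couples a samples-by-variants dosage matrix with variant
#' metadata (chromosome, 1-based position, effect/other allele, generating
#' allele frequency where known) and sample metadata (population label,
#' admixture fraction, covariates). All downstream modules consume this
#' container.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns, entries
#'   in `[0, 2]` (`NA` allowed for missing calls).
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `a1`
#'   (effect allele), `a2` (other allele) and optionally `freq`.
#' @param samples data.frame with column `sample_id` and optional metadata
#'   (`population`, `alpha`, ...).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, variants, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(variants)) stop2("variants must be a data.frame")
  need <- c("chrom", "pos", "id", "a1", "a2")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop2("variants is missing columns: ", paste(miss, collapse = ", "))
  if (ncol(dosage) != nrow(variants)) {
    stop2("dosage has ", ncol(dosage), " columns but variants has ",
          nrow(variants), " rows")
  }
  if (any(variants$pos < 1)) stop2("positions are 1-based and must be >= 1")
  if (any(variants$a1 == variants$a2)) stop2("a1 and a2 must differ")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop2("dosages must lie in [0, 2]")
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(dosage) %||%
                            paste0("s", seq_len(nrow(dosage))))
  }
  if (nrow(samples) != nrow(dosage)) stop2("samples does not match dosage rows")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  if (!is.null(x$samples$population)) {
    cat("populations:", paste(unique(x$samples$population), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param x genotype_panel.
#' @param i sample index (optional).
#' @param j variant index (optional).
#' @param ... unused.
#' @return genotype_panel restricted to the requested samples/variants.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  genotype_panel(x$dosage[i, j, drop = FALSE],
                 x$variants[j, , drop = FALSE],
                 x$samples[i, , drop = FALSE])
}

#' Realized effect-allele frequency of a panel
#'
#' @param panel a [genotype_panel()].
#' @return numeric vector of per-variant effect-allele frequencies
#'   (mean dosage / 2, missing calls excluded).
#' @export
panel_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}
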