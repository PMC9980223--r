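#' Validate and construct a variant panel
#'
#' A variant panel is a plain data.frame of per-variant GWAS metadata used
#' for LD clumping and polygenic index weights: `variant_id`, `chromosome`,
#' `position` (bp), `effect_allele`, `other_allele`, `weight` (per-allele
#' effect size), `p_value` and optionally `eaf`.
#'
#' @param panel data.frame with the columns above.
#' @return the validated data.frame (invisibly unchanged).
#' @export
variantPanel <- function(panel) {
  panel <- as.data.frame(panel)
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "weight", "p_value")
  miss <- setdiff(need, colnames(panel))
  if (length(miss))
    stop("variant panel is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$variant_id))
    stop("variant ids must be unique")
  if (any(!is.na(panel$p_value) &
          (panel$p_value <= 0 | panel$p_value > 1)))
    stop("p-values must lie in (0, 1]")
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect and other allele must differ")
  panel
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited GWAS summary file into a variant panel, with a
#' configurable mapping from file column names to the panel's canonical
#' roles.
#'
#' @param path path to a tab-delimited file.
#' @param columns named list/character vector mapping canonical names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `weight`, `se`, `p_value`, `eaf`) to column names in the
#'   file. Defaults assume the canonical names are used directly.
#' @return a [variantPanel()] data.frame (plus `se` when present).
#' @export
readGwasSummary <- function(path, columns = list()) {
  defaults <- c(variant_id = "variant_id", chromosome = "chromosome",
                position = "position", effect_allele = "effect_allele",
                other_allele = "other_allele", weight = "weight",
                se = "se", p_value = "p_value", eaf = "eaf")
  map <- defaults
  map[names(columns)] <- unlist(columns)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  out <- vector("list", 0L)
  for (canon in names(defaults)) {
    src <- map[[canon]]
    if (src %in% colnames(raw)) out[[canon]] <- raw[[src]]
    else if (canon %in% c("se", "eaf")) next
    else stop("GWAS summary file lacks required column '", src, "'")
  }
  variantPanel(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Empirical LD matrix from reference dosages
#'
#' Pairwise squared Pearson correlations between variant dosage columns,
#' the r-squared lookup consumed by [clumpVariants()].
#'
#' @param dosages numeric matrix, samples x variants, with variant ids as
#'   column names.
#' @return symmetric matrix of r-squared values with variant-id dimnames.
#' @export
ldFromDosages <- function(dosages) {
  if (is.null(colnames(dosages)))
    stop("dosage matrix must have variant ids as column names")
  r <- suppressWarnings(stats::cor(dosages))
  r[!is.finite(r)] <- 0  # monomorphic columns carry no LD information
  r^2
}

.ld_lookup <- function(ld) {
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    if (is.null(rownames(ld)) || is.null(colnames(ld)))
      stop("LD matrix must have variant-id dimnames")
    return(function(i, j) {
      if (!(i %in% rownames(ld)) || !(j %in% colnames(ld))) return(NA_real_)
      ld[i, j]
    })
  }
  stop("ld must be an r-squared matrix with variant-id dimnames or a ",
       "function(id1, id2)")
}

#' Greedy LD clumping of a variant panel
#'
#' Orders variants by ascending p-value (ties broken by chromosome, position,
#' then variant id, so the result does not depend on input row order) and
#' greedily accepts a variant unless an already-accepted variant on the same
#' chromosome lies within `window_kb` and has r-squared at or above
#' `r2_threshold` with it. Variants above `p_threshold` are removed first.
#'
#' The two clumping regimes used for index construction
#' (`r2_threshold = 0.01`) and for two-sample summary MR
#' (`r2_threshold = 0.001`) are parameterizations of this one operation.
#'
#' @param panel a [variantPanel()] data.frame.
#' @param ld r-squared lookup: a symmetric matrix with variant-id dimnames or
#'   a `function(id1, id2)`. A missing value for an in-window pair is an
#'   error; independence is never silently assumed.
#' @param p_threshold retain only variants with `p_value <= p_threshold`
#'   (default genome-wide significance, 5e-8).
#' @param window_kb clumping window in kilobases (default 10,000).
#' @param r2_threshold LD threshold (default 0.01).
#' @return the retained rows of `panel`, ordered by (p, chromosome, position,
#'   id).
#' @export
clumpVariants <- function(panel, ld, p_threshold = 5e-8, window_kb = 10000,
                          r2_threshold = 0.01) {
  panel <- variantPanel(panel)
  if (anyNA(panel$position) || anyNA(panel$chromosome))
    stop("clumping requires chromosome and position for every variant")
  lookup <- .ld_lookup(ld)
  cand <- panel[!is.na(panel$p_value) & panel$p_value <= p_threshold, ,
                drop = FALSE]
  if (!nrow(cand)) return(cand)
  ord <- order(cand$p_value, cand$chromosome, cand$position,
               cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    near <- kept[cand$chromosome[kept] == cand$chromosome[i] &
                   abs(cand$position[kept] - cand$position[i]) <= window_bp]
    ok <- TRUE
    for (j in near) {
      r2 <- lookup(cand$variant_id[i], cand$variant_id[j])
      if (is.na(r2))
        stop(sprintf("no r-squared available for in-window pair %s / %s",
                     cand$variant_id[i], cand$variant_id[j]))
      if (r2 >= r2_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a weighted polygenic index
#'
#' Raw score per sample is the weight-by-dosage sum over the panel's
#' variants, `sum_j weight_j * dosage_ij`, with dosages counted on the
#' panel's effect allele (harmonize upstream). Standardized scores are
#' z-units within the supplied sample, the scale on which per-SD effects are
#' reported.
#'
#' @param dosages numeric matrix, samples x variants, variant ids as column
#'   names, sample ids as rownames (defaults generated).
#' @param panel a [variantPanel()] whose `variant_id`s must all be present in
#'   `dosages`.
#' @return data.frame with `sample_id`, `raw` and `standardized` columns.
#' @export
buildPgi <- function(dosages, panel) {
  panel <- variantPanel(panel)
  if (is.null(colnames(dosages)))
    stop("dosage matrix must have variant ids as column names")
  miss <- setdiff(panel$variant_id, colnames(dosages))
  if (length(miss))
    stop("variants in panel absent from dosages: ",
         paste(miss, collapse = ", "))
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dosages)))
  raw <- as.numeric(dosages[, panel$variant_id, drop = FALSE] %*%
                      panel$weight)
  data.frame(sample_id = ids, raw = raw, standardized = .standardize(raw),
             stringsAsFactors = FALSE)
}

#' Polygenic indices for every role of a trio cohort
#'
#' Builds mother, father and child polygenic indices from a cohort,
#' standardizing within each role separately.
#'
#' @param cohort a [TrioCohort-class].
#' @param panel optional [variantPanel()]; when omitted, all cohort variants
#'   are used with unit weights.
#' @return data.frame with `family_id`, raw and standardized PGI columns per
#'   role (`pgi_mother`, `pgi_father`, `pgi_child` are the standardized
#'   scores).
#' @export
cohortPgis <- function(cohort, panel = NULL) {
  if (is.null(panel)) {
    vi <- variantInfo(cohort)
    panel <- data.frame(variant_id = vi$variant_id,
                        chromosome = vi$chromosome, position = vi$position,
                        effect_allele = vi$effect_allele,
                        other_allele = vi$other_allele,
                        weight = if ("weight" %in% colnames(vi)) vi$weight
                                 else rep(1, nrow(vi)),
                        p_value = rep(1, nrow(vi)),
                        stringsAsFactors = FALSE)
  }
  out <- data.frame(family_id = familyIds(cohort), stringsAsFactors = FALSE)
  for (role in c("mother", "father", "child")) {
    pgi <- buildPgi(dosageMatrix(cohort, role), panel)
    out[[paste0("pgi_raw_", role)]] <- pgi$raw
    out[[paste0("pgi_", role)]] <- pgi$standardized
  }
  out
}
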