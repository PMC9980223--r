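# File formats. Tab-delimited is the canonical dialect: numeric output with
# 6 significant digits, missing values written as "NA". See inst/FORMATS.md.

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

#' Read a delimited dosage matrix
#'
#' Expects a tab-delimited file whose first column holds sample ids and whose
#' header names the variants. Dosages are validated to lie in `[0, 2]`;
#' non-integer values (imputed dosages) are rejected unless
#' `allow_imputed = TRUE`.
#'
#' @param path input file.
#' @param allow_imputed accept fractional dosages (default `FALSE`:
#'   hard-call mode).
#' @return numeric matrix, samples x variants, with sample-id rownames.
#' @export
readDosageMatrix <- function(path, allow_imputed = FALSE) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("dosage file needs a sample-id column plus ",
                          "at least one variant column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric dosage at row %d, column '%s'", bad[1],
                 colnames(m)[bad[2]]))
  }
  if (anyNA(m) || min(m) < 0 || max(m) > 2)
    stop("dosages must lie in [0, 2] with no missing values")
  if (!allow_imputed && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("fractional dosage at row %d, column '%s'; use ",
                        "allow_imputed = TRUE for imputed dosages"),
                 bad[1], colnames(m)[bad[2]]))
  }
  rownames(m) <- ids
  m
}

#' Write a dosage matrix
#'
#' @param dosages numeric matrix, samples x variants, with sample-id
#'   rownames and variant-id colnames.
#' @param path output file.
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @return the path, invisibly.
#' @export
writeDosageMatrix <- function(dosages, path, id_column = "sample_id") {
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dosages)))
  df <- data.frame(ids, as.data.frame(dosages), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  .write_tsv(df, path)
}

#' Read a FAM-like pedigree of trios
#'
#' Expects columns `family_id`, `child_id`, `father_id`, `mother_id` (FAM
#' column order). Rows missing a parent or child id are dropped with a
#' warning (incomplete trios); a child appearing in two families is an error.
#'
#' @param path input file.
#' @return data.frame of complete trio links.
#' @export
readPedigree <- function(path) {
  df <- .read_tsv(path)
  need <- c("family_id", "child_id", "father_id", "mother_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("pedigree lacks column(s): ", paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(df[, need]) |
    df$child_id == "" | df$father_id == "" | df$mother_id == ""
  if (any(incomplete)) {
    warning(sum(incomplete), " incomplete trio(s) dropped from pedigree")
    df <- df[!incomplete, , drop = FALSE]
  }
  dup <- duplicated(df$child_id)
  if (any(dup))
    stop("child id(s) appear in more than one family: ",
         paste(unique(df$child_id[dup]), collapse = ", "))
  rownames(df) <- NULL
  df[, need]
}

#' Read a phenotype/covariate table
#'
#' First column is the sample/family id; remaining columns are phenotypes
#' or covariates.
#'
#' @param path input file.
#' @return data.frame.
#' @export
readPhenotypeTable <- function(path) {
  df <- .read_tsv(path)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate id(s) in phenotype table")
  df
}

#' Write a TrioCohort to delimited files
#'
#' Emits three dosage matrices (`dosage_mother.tsv`, `dosage_father.tsv`,
#' `dosage_child.tsv`, keyed by role-specific sample ids), a FAM-like
#' pedigree (`pedigree.tsv`), a phenotype/covariate table
#' (`phenotypes.tsv`), a variant table (`variants.tsv`) and a provenance
#' record (`provenance.json`).
#'
#' @param cohort a [TrioCohort-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @seealso [readTrioCohort()]
#' @export
writeTrioCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fam <- familyIds(cohort)
  ids <- list(mother = paste0(fam, "_m"), father = paste0(fam, "_f"),
              child = paste0(fam, "_c"))
  for (role in names(ids)) {
    d <- dosageMatrix(cohort, role)
    rownames(d) <- ids[[role]]
    writeDosageMatrix(d, file.path(dir, paste0("dosage_", role, ".tsv")))
  }
  ped <- data.frame(family_id = fam, child_id = ids$child,
                    father_id = ids$father, mother_id = ids$mother,
                    stringsAsFactors = FALSE)
  .write_tsv(ped, file.path(dir, "pedigree.tsv"))
  ph <- as.data.frame(SummarizedExperiment::colData(cohort))
  .write_tsv(ph, file.path(dir, "phenotypes.tsv"))
  .write_tsv(variantInfo(cohort), file.path(dir, "variants.tsv"))
  cfg <- simParams(cohort)
  writeProvenance(file.path(dir, "provenance.json"),
                  config = if (is.null(cfg)) NULL else .config_as_list(cfg),
                  seed = if (is.null(cfg)) NA_integer_ else cfg@seed)
  invisible(dir)
}

#' Read a TrioCohort back from delimited files
#'
#' Round-trip reader for [writeTrioCohort()] output; also accepts
#' user-supplied files in the same layout. Trio members named in the
#' pedigree must exist in the dosage matrices.
#'
#' @param dir directory holding the files.
#' @param allow_imputed passed to [readDosageMatrix()].
#' @return a [TrioCohort-class].
#' @export
readTrioCohort <- function(dir, allow_imputed = FALSE) {
  ped <- readPedigree(file.path(dir, "pedigree.tsv"))
  mats <- lapply(c(mother = "mother", father = "father", child = "child"),
                 function(role) readDosageMatrix(
                   file.path(dir, paste0("dosage_", role, ".tsv")),
                   allow_imputed = allow_imputed))
  idcol <- c(mother = "mother_id", father = "father_id", child = "child_id")
  for (role in names(mats)) {
    absent <- setdiff(ped[[idcol[[role]]]], rownames(mats[[role]]))
    if (length(absent))
      stop("pedigree ", role, " id(s) missing from dosage matrix: ",
           paste(absent, collapse = ", "))
    mats[[role]] <- mats[[role]][ped[[idcol[[role]]]], , drop = FALSE]
  }
  ph <- readPhenotypeTable(file.path(dir, "phenotypes.tsv"))
  absent <- setdiff(ped$family_id, ph$family_id)
  if (length(absent))
    stop("pedigree family id(s) missing from phenotype table: ",
         paste(absent, collapse = ", "))
  ph <- ph[match(ped$family_id, ph$family_id), , drop = FALSE]
  vpath <- file.path(dir, "variants.tsv")
  variants <- if (file.exists(vpath)) .read_tsv(vpath) else NULL
  phen_cols <- intersect(c("exposure_mother", "exposure_father",
                           "outcome_child"), colnames(ph))
  cov_cols <- setdiff(colnames(ph), c("family_id", phen_cols))
  TrioCohort(mats$mother, mats$father, mats$child, variants = variants,
             phenotypes = if (length(phen_cols))
               ph[, phen_cols, drop = FALSE] else NULL,
             covariates = if (length(cov_cols))
               as.matrix(ph[, cov_cols, drop = FALSE]) else NULL,
             familyIds = ped$family_id)
}

#' Export dosages as a minimal VCF
#'
#' Writes hard-call dosages for one role as diploid GT records (VCFv4.2,
#' unphased), one sample column per family member of that role. Fractional
#' dosages cannot be represented and are an error.
#'
#' @param cohort a [TrioCohort-class].
#' @param role `"mother"`, `"father"` or `"child"`.
#' @param path output file (plain text).
#' @return the path, invisibly.
#' @export
writeVcfDosages <- function(cohort, role, path) {
  d <- dosageMatrix(cohort, role)
  if (any(d != round(d)))
    stop("VCF GT export requires hard-call dosages")
  vi <- variantInfo(cohort)
  gt <- c("0/0", "0/1", "1/1")
  ids <- paste0(familyIds(cohort), "_", substr(role, 1, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(ncol(d))) {
    row <- c(vi$chromosome[j], vi$position[j], vi$variant_id[j],
             vi$other_allele[j], vi$effect_allele[j], ".", "PASS", ".",
             "GT", gt[d[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Maps GT (effect-allele counts against ALT) or DS fields to a dosage
#' matrix using the vcfR package. Multiallelic records are rejected.
#'
#' @param path a VCF file.
#' @return numeric matrix, samples x variants.
#' @export
readVcfDosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfDosages requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multiallelic records are not supported")
  fmt <- v@gt[, "FORMAT"]
  if (all(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
  }
  out <- t(ds)
  colnames(out) <- vcfR::getID(v)
  out
}

.config_as_list <- function(config) {
  nms <- slotNames("SimConfig")
  stats::setNames(lapply(nms, function(s) slot(config, s)), nms)
}

#' Read a simulation configuration from a YAML file
#'
#' Key-value file mirroring the [simConfig()] argument names
#' (`nCouples`, `nSnps`, `alleleFreqs`, `assortmentPhi`, ...).
#'
#' @param path YAML file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(simConfig, vals)
}

#' Write a provenance record
#'
#' Every run writes a JSON record of the configuration, package version and
#' seed beside its outputs.
#'
#' @param path output JSON file.
#' @param config list of configuration values (or `NULL`).
#' @param seed the seed used.
#' @param ... further fields to record.
#' @return the path, invisibly.
#' @export
writeProvenance <- function(path, config = NULL, seed = NA_integer_, ...) {
  rec <- list(package = "triomr",
              version = as.character(utils::packageVersion("triomr")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config, ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
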