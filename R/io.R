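# Plain-text readers/writers for the pipeline's standard shapes. All
# numeric output is printed with 17 significant digits so that
# write -> read round-trips reproduce doubles bit-exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read trio dosage matrices as TSV
#'
#' One row per family; columns are `family_id`, `sex_child`, then
#' `<member>:<snp_id>` integer dosages for members child, mother, father.
#'
#' @param cohort a `trio_cohort`.
#' @param path output file.
#' @return the path (writer) or a `trio_cohort` (reader).
#' @export
write_trio_dosages <- function(cohort, path) {
  stopifnot(inherits(cohort, "trio_cohort"))
  blocks <- lapply(c("child", "mother", "father"), function(m) {
    d <- cohort[[paste0("dosage_", m)]]
    colnames(d) <- paste0(m, ":", colnames(d))
    d
  })
  df <- data.frame(
    family_id = cohort$family_id,
    sex_child = cohort$sex_child,
    do.call(cbind, blocks),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_exact(df, path)
}

#' @rdname write_trio_dosages
#' @export
read_trio_dosages <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  get_member <- function(m) {
    cols <- grep(paste0("^", m, ":"), names(df), value = TRUE)
    mat <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(mat) <- "integer"
    dimnames(mat) <- list(df$family_id, sub("^[a-z]+:", "", cols))
    mat
  }
  structure(
    list(
      family_id = df$family_id,
      dosage_child = get_member("child"),
      dosage_mother = get_member("mother"),
      dosage_father = get_member("father"),
      sex_child = as.integer(df$sex_child)
    ),
    class = "trio_cohort"
  )
}

#' Write and read a GWAS weight set TSV
#'
#' Header: `snp_id effect_allele other_allele weight se provenance`.
#'
#' @param ws a `weight_set`.
#' @param path file path.
#' @export
write_weight_set <- function(ws, path) {
  write_tsv_exact(
    ws[, c("snp_id", "effect_allele", "other_allele", "weight", "se",
           "provenance")],
    path
  )
}

#' @rdname write_weight_set
#' @export
read_weight_set <- function(path) {
  ws <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "weight", "se",
            "provenance")
  missing_cols <- setdiff(need, names(ws))
  if (length(missing_cols)) {
    stop_invalid("weight-set file lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  class(ws) <- c("weight_set", "data.frame")
  ws
}

#' Write and read a methylation beta matrix with its sample sheet
#'
#' The beta TSV has one row per CpG and one column per sample
#' (first column `cpg_id`); the sample sheet carries `sample_id`,
#' `array_label`, `plate` and the seven cell proportions.
#'
#' @param meth a `methylome`.
#' @param beta_path,sheet_path output files.
#' @export
write_methylome <- function(meth, beta_path, sheet_path) {
  stopifnot(inherits(meth, "methylome"))
  bdf <- data.frame(
    cpg_id = meth$cpg_id,
    t(meth$beta),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_exact(bdf, beta_path)
  sheet <- data.frame(
    sample_id = meth$sample_id,
    array_label = meth$array_label,
    plate = meth$plate,
    meth$cell_props,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_exact(sheet, sheet_path)
  invisible(c(beta_path, sheet_path))
}

#' @rdname write_methylome
#' @export
read_methylome <- function(beta_path, sheet_path) {
  bdf <- utils::read.delim(beta_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sheet <- utils::read.delim(sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  beta <- t(as.matrix(bdf[, -1, drop = FALSE]))
  colnames(beta) <- bdf$cpg_id
  rownames(beta) <- colnames(bdf)[-1]
  beta <- beta[match(sheet$sample_id, rownames(beta)), , drop = FALSE]
  cells <- as.matrix(sheet[, c("B", "CD4T", "CD8T", "Gran", "Mono", "NK",
                               "nRBC")])
  rownames(cells) <- sheet$sample_id
  structure(
    list(
      beta = beta,
      cpg_id = bdf$cpg_id,
      sample_id = sheet$sample_id,
      array_label = sheet$array_label,
      plate = sheet$plate,
      cell_props = cells
    ),
    class = "methylome"
  )
}

#' Write and read an EWAS weight table (`cpg_id`, `weight`, optional `se`)
#' @param ww an `ewas_weights` data.frame.
#' @param path file path.
#' @export
write_ewas_weights <- function(ww, path) {
  write_tsv_exact(ww, path)
}

#' @rdname write_ewas_weights
#' @export
read_ewas_weights <- function(path) {
  ww <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cpg_id", "weight") %in% names(ww))) {
    stop_invalid("EWAS weight file needs columns cpg_id and weight")
  }
  class(ww) <- c("ewas_weights", "data.frame")
  ww
}

#' Write and read the phenotype/mediator table
#' @param phen a `family_phenotypes` data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phen, path) {
  write_tsv_exact(as.data.frame(phen), path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  phen <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(phen) <- c("family_phenotypes", "data.frame")
  phen
}

#' Read effect-allele dosages from a VCF with a DS FORMAT field
#'
#' Accepts fractional imputed dosages on input (the simulator itself only
#' emits hard calls). Requires the `vcfR` package.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with `dosages` (samples x SNPs), `panel` (snp_id, REF as
#'   other allele, ALT as effect allele).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_invalid("read_dosage_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  dosages <- t(ds)
  colnames(dosages) <- fix[, "ID"]
  list(
    dosages = dosages,
    panel = data.frame(
      snp_id = fix[, "ID"],
      effect_allele = fix[, "ALT"],
      other_allele = fix[, "REF"],
      stringsAsFactors = FALSE
    )
  )
}
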