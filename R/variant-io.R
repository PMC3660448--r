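# Readers and writers for the pipeline's file formats: VCF genotypes,
# tab-separated variant annotations, phenotype/covariate tables and
# results tables. Annotation functional classes follow the conventional
# vocabulary of exome annotation tools.

.FUNC_CLASSES <- c("intronic", "intergenic", "missense", "synonymous",
                   "utr3", "utr5")

#' Read diploid genotypes from a VCF file
#'
#' Parses GT fields of a VCF (v4.x) into a [genotype_matrix]. Calls may be
#' unphased (`0/1`) or phased (`0|1`); `./.` and `.` are treated as missing.
#' Multi-allelic records are rejected: the pipeline analyses biallelic SNVs
#' only.
#'
#' @param vcf_path path to a VCF file (plain text or bgzipped).
#' @param stratum_map named character vector mapping every subject id in
#'   the VCF to its ancestry stratum.
#' @return a [genotype_matrix] with variant ids `chrom:pos` (or the VCF ID
#'   field where present and not ".").
#' @export
read_genotypes <- function(vcf_path, stratum_map) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) at ",
         paste(fix[multi, "CHROM"], fix[multi, "POS"],
               sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotype fields")
  ids <- fix[, "ID"]
  vid <- ifelse(is.na(ids) | ids == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = ":"), ids)
  subs <- colnames(gt)
  missing_sub <- setdiff(subs, names(stratum_map))
  if (length(missing_sub))
    stop("subjects in VCF absent from stratum map: ",
         paste(missing_sub, collapse = ", "))

  # GT string -> alt-allele count; any '.' allele makes the call missing
  code <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "."))
        return(NA_integer_)
      if (length(a) != 2) stop("non-diploid genotype call: ",
                               paste(a, collapse = "/"), call. = FALSE)
      sum(a == "1")
    }, integer(1))
  }
  dos <- apply(gt, 2, code)
  if (is.null(dim(dos)))
    dos <- matrix(dos, nrow = 1, dimnames = list(NULL, subs))
  dos <- t(dos)                       # subjects x variants
  colnames(dos) <- vid
  rownames(dos) <- subs
  genotype_matrix(dos, stratum = stratum_map[subs])
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only genotype columns; the stored
#' alternate-allele dosages are written as unphased calls (`0/0`, `0/1`,
#' `1/1`, `./.`). Round-trips through [read_genotypes()].
#'
#' @param gm a [genotype_matrix].
#' @param annotations data.frame with columns `chrom`, `pos`, `rsid`,
#'   `ref_allele`, `alt_allele`, one row per variant in `gm` order.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, annotations, path) {
  stopifnot(nrow(annotations) == ncol(gm$dosage))
  gt <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", subject_ids(gm)), collapse = "\t"))
  body <- vapply(seq_len(ncol(gm$dosage)), function(j) {
    d <- gm$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt[d + 1L])
    rsid <- annotations$rsid[j]
    paste(c(annotations$chrom[j], annotations$pos[j],
            if (is.na(rsid) || rsid == "-") "." else rsid,
            annotations$ref_allele[j], annotations$alt_allele[j],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write a variant annotation table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `rsid` (`-` when
#' absent), `ref_allele`, `alt_allele`, `func_class`, `novel`, and an
#' optional free-text `prediction_label` which is carried, never computed.
#'
#' @param path file path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  req <- c("chrom", "pos", "rsid", "ref_allele", "alt_allele",
           "func_class", "novel")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$func_class), .FUNC_CLASSES)
  if (length(bad)) stop("unknown functional class: ",
                        paste(bad, collapse = ", "))
  ann$novel <- as.logical(ann$novel)
  ann
}

#' @rdname read_annotations
#' @param annotations data.frame of annotations.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset annotations by functional class
#'
#' Order-preserving filter; errors on a class label outside the known
#' vocabulary so typos never silently yield an empty set. An empty result
#' is allowed (downstream burden tests refuse to run on it).
#'
#' @param annotations annotation data.frame with a `func_class` column.
#' @param classes non-empty subset of
#'   `c("intronic","intergenic","missense","synonymous","utr3","utr5")`.
#' @return the matching rows of `annotations`.
#' @export
filter_by_class <- function(annotations, classes) {
  if (length(classes) == 0) stop("'classes' must be non-empty")
  bad <- setdiff(classes, .FUNC_CLASSES)
  if (length(bad)) stop("unknown functional class: ",
                        paste(bad, collapse = ", "))
  annotations[annotations$func_class %in% classes, , drop = FALSE]
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header: `subject_id`, `stratum`, phenotypes
#' `pheno_col`, `pheno_epi`, `pheno_adp` (percent aggregation, 0-100) and
#' covariates `age`, `sex`, `diabetes`, `hypertension`, `bmi`, `ldl`,
#' `smoking`, `fibrinogen`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  coh <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "stratum", "pheno_col", "pheno_epi", "pheno_adp",
           .COVARIATES)
  miss <- setdiff(req, names(coh))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  coh
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an association results table
#'
#' Tab-separated, one row per variant or burden set. Missing rsIDs are
#' serialised as `-`, untestable (monomorphic) p-values as `NA`, and very
#' small p-values in scientific notation; the table round-trips through
#' `read_results_table()`.
#'
#' @param results data.frame of association results.
#' @param path output path.
#' @export
write_results_table <- function(results, path) {
  out <- results
  if ("rsid" %in% names(out))
    out$rsid[is.na(out$rsid) | out$rsid == ""] <- "-"
  for (col in intersect(c("p_value", "maf", "statistic"), names(out)))
    out[[col]] <- vapply(out[[col]], function(x) {
      if (is.na(x)) "NA" else format(x, digits = 6, scientific = x != 0 && abs(x) < 1e-4)
    }, character(1))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  for (col in intersect(c("p_value", "maf", "statistic"), names(res)))
    res[[col]] <- as.numeric(res[[col]])
  res
}
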