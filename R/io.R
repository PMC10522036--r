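## Application-mode I/O: VCF genotypes, delimited phenotypes, VCF export.

#' Load a genomic region from a VCF file as a dosage matrix
#'
#' Reads the GT field for all records of one region (1-based inclusive
#' coordinates, the VCF convention) and converts to minor-allele dosages.
#' Missing genotypes are imputed to twice the variant's observed alternate
#' allele frequency; multiallelic records are skipped with a warning;
#' columns are flipped to count the minor allele.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param region Region string \code{"chrom:start-end"}, or \code{NULL} for
#'   all records.
#' @param samples Optional character vector restricting/ordering samples.
#' @return A \code{genotype_matrix}; row names carry sample ids.
#' @export
load_region_from_vcf <- function(vcf_path, region = NULL, samples = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    parts <- regmatches(region,
                        regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(parts) != 4L)
      stop("region must be of the form chrom:start-end", call. = FALSE)
    keep <- fix[, "CHROM"] == parts[2] &
      pos >= as.numeric(parts[3]) & pos <= as.numeric(parts[4])
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi & keep)) {
    warning(sum(multi & keep), " multiallelic record(s) skipped")
    keep <- keep & !multi
  }
  if (!any(keep)) stop("no variants in region", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing))
      stop("samples absent from VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    gt <- gt[, samples, drop = FALSE]
  }
  ## alt-allele dosage; "." anywhere in the call means missing
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  af <- rowMeans(dose, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  for (i in seq_len(nrow(dose))) {
    miss <- is.na(dose[i, ])
    if (any(miss)) dose[i, miss] <- 2 * af[i]
  }
  G <- t(dose)
  flip <- af > 0.5
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  gm <- new_genotype_matrix(G, maf = pmin(af, 1 - af), positions = pos[keep])
  rownames(gm$G) <- colnames(gt)
  gm
}

#' Load phenotypes and covariates from a delimited table
#'
#' Expects a header with columns \code{id}, \code{phenotype} and optional
#' covariate columns. The phenotype must be binary 0/1. When \code{ids} is
#' given (e.g. the VCF sample order), rows are matched by id, not position.
#'
#' @param path Path to a tab/comma-delimited table.
#' @param ids Optional sample ids fixing the output order.
#' @return A \code{phenotype_set} with \code{y}, \code{X} (NULL if no
#'   covariates), \code{ids}.
#' @export
load_phenotypes <- function(path, ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1L)
    df <- utils::read.table(path, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE)
  need <- c("id", "phenotype")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns 'id' and 'phenotype'",
         call. = FALSE)
  if (!all(df$phenotype %in% c(0, 1)))
    stop("phenotype must be binary 0/1; offending values: ",
         paste(unique(setdiff(df$phenotype, 0:1)), collapse = ", "),
         call. = FALSE)
  if (!is.null(ids)) {
    missing <- setdiff(ids, df$id)
    if (length(missing))
      stop("ids missing from phenotype table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    df <- df[match(ids, df$id), , drop = FALSE]
  }
  covar_cols <- setdiff(names(df), need)
  X <- if (length(covar_cols))
    as.matrix(df[, covar_cols, drop = FALSE]) else NULL
  structure(list(y = as.integer(df$phenotype), X = X, ids = df$id,
                 n_cases = sum(df$phenotype == 1),
                 n_controls = sum(df$phenotype == 0),
                 beta0 = NA_real_),
            class = "phenotype_set")
}

#' Export a genotype matrix as a VCF file
#'
#' Writes a minimal VCF 4.2 with GT-only genotype fields on one
#' pseudo-chromosome; dosages round-trip exactly through
#' \code{\link{load_region_from_vcf}} in the absence of missing data.
#' Internal 0-based positions are shifted to the 1-based VCF convention.
#'
#' @param gm A \code{genotype_matrix}.
#' @param file Output path.
#' @param chrom Chromosome name (default \code{"1"}).
#' @param ids Sample ids (default \code{S1..Sn}).
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(gm, file, chrom = "1", ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(ids)) ids <- paste0("S", seq_len(gm$n))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", chrom),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- vapply(seq_len(gm$m), function(j) {
    paste(c(chrom, format(gm$positions[j] + 1, scientific = FALSE),
            sprintf("var%d", j), "A", "T", ".", "PASS", ".", "GT",
            gt_code[round(gm$G[, j]) + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Test one region with an ensemble
#'
#' Application-mode entry: runs every member test on the genotypes and
#' phenotypes and combines them into the min-p Bonferroni ensemble p-value.
#'
#' @param gm A \code{genotype_matrix} (e.g. from
#'   \code{\link{load_region_from_vcf}}).
#' @param phen A \code{phenotype_set} (e.g. from
#'   \code{\link{load_phenotypes}}).
#' @param registry Test registry; defaults to all fifteen core tests.
#' @param members Member ids of the ensemble (default: all registry tests).
#' @return A list with \code{ensemble_pvalue} and \code{members} (data frame
#'   of per-member p-values and timings).
#' @export
test_region <- function(gm, phen, registry = default_registry(),
                        members = names(registry)) {
  registry <- registry[members]
  nf <- tryCatch(fit_null_model(phen$y, phen$X), error = function(e) NULL)
  res <- lapply(registry, function(spec)
    run_test_safe(spec, gm$G, phen$y, phen$X, maf = gm$maf, null_fit = nf))
  tab <- data.frame(test_id = vapply(res, `[[`, "", "test_id"),
                    pvalue = vapply(res, `[[`, 0, "pvalue"),
                    elapsed = vapply(res, `[[`, 0, "elapsed"),
                    row.names = NULL)
  list(ensemble_pvalue = ensemble_pvalue(tab$pvalue), members = tab)
}

#' Write a run manifest
#'
#' Records seed, package version, configuration and output paths of a run
#' as a JSON file; every listed output must exist.
#'
#' @param path Manifest output path.
#' @param seed Run seed.
#' @param config Named list describing the run.
#' @param outputs Character vector of produced file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(), outputs = character()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest lists missing outputs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  manifest <- list(
    seed = seed,
    version = as.character(utils::packageVersion("rvensemble")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
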