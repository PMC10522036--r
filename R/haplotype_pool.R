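#' Generate a synthetic haplotype pool
#'
#' Builds a pool of binary haplotypes over a genomic span under a neutral
#' site-frequency spectrum: the derived-allele count at each site is drawn
#' with probability proportional to \code{1/i} over \code{i = 1, ...,
#' n_hap - 1}, carriers are chosen uniformly without replacement, and site
#' positions are uniform on \code{[0, span)} then sorted. The default pool
#' (10,000 haplotypes over 1 Mb with 20 variant sites per kb) emulates the
#' rare-variant-dominated spectrum of a coalescent simulation of a European
#' population at the scale consumed by region-based tests: more than half of
#' all sites have minor-allele frequency below 0.01. No linkage
#' disequilibrium, recombination or demography is modelled; externally
#' produced haplotypes can be imported with \code{\link{read_haplotype_pool}}.
#'
#' Coordinates are 0-based and regions are half-open windows.
#'
#' @param n_hap Number of haplotypes (default 10,000).
#' @param span Region length in base pairs (default 1e6).
#' @param n_sites Number of polymorphic sites (default \code{span / 1000 * 20},
#'   i.e. a density of 20 variants per kb).
#' @param sfs Site-frequency-spectrum model; \code{"neutral"} (probability
#'   proportional to 1/i) or a numeric vector of unnormalised weights over
#'   derived-allele counts \code{1..n_hap-1}.
#' @param seed Integer seed; the pool is bit-identical for a fixed seed.
#' @return A \code{haplotype_pool}: list with \code{alleles} (sparse
#'   \code{n_hap x n_sites} 0/1 matrix, haplotypes in rows), \code{positions}
#'   (strictly increasing bp coordinates), \code{span}, \code{n_hap},
#'   \code{daf} (per-site derived-allele frequency).
#' @export
generate_haplotype_pool <- function(n_hap = 10000L, span = 1e6,
                                    n_sites = round(span / 1000 * 20),
                                    sfs = "neutral", seed = 1L) {
  n_hap <- as.integer(n_hap); n_sites <- as.integer(n_sites)
  if (is.na(n_hap) || n_hap < 2L) stop("n_hap must be >= 2", call. = FALSE)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (span <= 0) stop("span must be positive", call. = FALSE)
  if (identical(sfs, "neutral")) {
    w <- 1 / seq_len(n_hap - 1L)
  } else {
    w <- as.numeric(sfs)
    if (length(w) != n_hap - 1L || any(w < 0) || sum(w) <= 0)
      stop("custom sfs must be ", n_hap - 1L, " non-negative weights",
           call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng$restore(), add = TRUE)

  if (n_sites > floor(span))
    stop("n_sites may not exceed span (one site per bp at most)", call. = FALSE)
  ## distinct bp coordinates keep positions strictly increasing
  positions <- sort(sample.int(floor(span), n_sites)) - 1

  counts <- sample.int(n_hap - 1L, n_sites, replace = TRUE, prob = w)
  ## carriers per site, assembled into one sparse matrix
  carriers <- lapply(counts, function(k) sample.int(n_hap, k))
  i_idx <- unlist(carriers, use.names = FALSE)
  j_idx <- rep.int(seq_len(n_sites), counts)
  alleles <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                                  dims = c(n_hap, n_sites))
  new_haplotype_pool(alleles, positions, span)
}

new_haplotype_pool <- function(alleles, positions, span) {
  daf <- Matrix::colMeans(alleles)
  structure(list(alleles = alleles,
                 positions = as.numeric(positions),
                 span = as.numeric(span),
                 n_hap = nrow(alleles),
                 n_sites = ncol(alleles),
                 daf = as.numeric(daf)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes, %d sites over %g bp\n",
              x$n_hap, x$n_sites, x$span))
  cat(sprintf("  MAF < 0.01 at %.1f%% of sites\n",
              100 * mean(pmin(x$daf, 1 - x$daf) < 0.01)))
  invisible(x)
}

#' Draw a random region from a haplotype pool
#'
#' Picks a uniform start offset and returns the sites falling in the
#' half-open window \code{[start, start + size)}, retrying until the window
#' holds at least \code{min_variants} sites and its start has not been used
#' before (regions are kept distinct across the replicates of one experiment
#' by start offset).
#'
#' @param pool A \code{\link{generate_haplotype_pool}} result.
#' @param size Region size in bp (typical values 1000, 3000, 5000).
#' @param min_variants Minimum number of variant sites (default 2).
#' @param exclusions Numeric vector of start offsets already used.
#' @param max_attempts Attempts before giving up.
#' @return A \code{region_draw}: list with \code{start}, \code{size},
#'   \code{site_indices}, \code{m}.
#' @export
draw_region <- function(pool, size, min_variants = 2L, exclusions = numeric(),
                        max_attempts = 100L) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (size > pool$span) stop("region size exceeds pool span", call. = FALSE)
  if (min_variants < 2L) stop("min_variants must be >= 2", call. = FALSE)
  for (attempt in seq_len(max_attempts)) {
    start <- floor(stats::runif(1, 0, pool$span - size + 1))
    if (start %in% exclusions) next
    idx <- which(pool$positions >= start & pool$positions < start + size)
    if (length(idx) >= min_variants) {
      return(structure(list(start = start, size = size, site_indices = idx,
                            m = length(idx)),
                       class = "region_draw"))
    }
  }
  stop(region_unavailable_error(size, max_attempts))
}

region_unavailable_error <- function(size, attempts) {
  structure(class = c("region_unavailable_error", "error", "condition"),
            list(message = sprintf(
              "no admissible region of %g bp found in %d attempts",
              size, attempts), call = NULL))
}

#' Select analysed variants by frequency mode
#'
#' Under \code{"rare_only"} keeps variants with MAF strictly below the
#' cutoff; under \code{"rare_and_common"} keeps all variants. A rare-only
#' set of fewer than two variants is a degenerate region.
#'
#' @param mafs Per-variant minor-allele frequencies.
#' @param cutoff Causal MAF cutoff in (0, 0.5].
#' @param mode \code{"rare_only"} or \code{"rare_and_common"}.
#' @return Integer indices of the kept variants.
#' @export
select_variants <- function(mafs, cutoff = 0.01,
                            mode = c("rare_only", "rare_and_common")) {
  mode <- match.arg(mode)
  if (cutoff <= 0 || cutoff > 0.5) stop("cutoff must be in (0, 0.5]", call. = FALSE)
  if (mode == "rare_and_common") return(seq_along(mafs))
  keep <- which(mafs < cutoff)
  if (length(keep) < 2L) stop(degenerate_region_error(length(keep)))
  keep
}

degenerate_region_error <- function(m) {
  structure(class = c("degenerate_region_error", "error", "condition"),
            list(message = sprintf(
              "degenerate region: %d analysable variant(s), need >= 2", m),
              call = NULL))
}

#' Assemble a dosage genotype matrix from haplotype pairs
#'
#' Each individual is the sum of two haplotypes at the region's sites,
#' counted on the minor allele: sites whose derived-allele frequency in the
#' pool exceeds 0.5 are flipped so that dosages count copies of the minor
#' allele.
#'
#' @param pool A haplotype pool.
#' @param region A \code{\link{draw_region}} result.
#' @param hap_pairs Integer matrix with two columns (haplotype indices per
#'   individual); the two indices of an individual must differ.
#' @return A \code{genotype_matrix}: list with \code{G} (n x m dosage matrix,
#'   entries 0/1/2), \code{maf} (pool minor-allele frequency per variant),
#'   \code{positions}.
#' @export
assemble_genotypes <- function(pool, region, hap_pairs) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(region, "region_draw"))
  hap_pairs <- matrix(as.integer(hap_pairs), ncol = 2L)
  if (any(hap_pairs < 1L) || any(hap_pairs > pool$n_hap))
    stop("haplotype index out of range", call. = FALSE)
  if (any(hap_pairs[, 1] == hap_pairs[, 2]))
    stop("an individual's two haplotypes must be distinct", call. = FALSE)
  H <- region_haplotypes(pool, region)
  G <- H[hap_pairs[, 1], , drop = FALSE] + H[hap_pairs[, 2], , drop = FALSE]
  daf <- pool$daf[region$site_indices]
  flip <- daf > 0.5
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  new_genotype_matrix(G, maf = pmin(daf, 1 - daf),
                      positions = pool$positions[region$site_indices])
}

## Dense 0/1 haplotype submatrix for a region (all pool haplotypes x sites).
## Columns are extracted straight from the CsparseMatrix slots: the generic
## "[" method is far too slow for the per-replicate access pattern.
region_haplotypes <- function(pool, region) {
  A <- pool$alleles
  idx <- region$site_indices
  out <- matrix(0, nrow(A), length(idx))
  p <- A@p; i <- A@i
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (p[j + 1L] > p[j]) out[i[(p[j] + 1L):p[j + 1L]] + 1L, k] <- 1
  }
  out
}

new_genotype_matrix <- function(G, maf, positions) {
  structure(list(G = G, maf = as.numeric(maf),
                 positions = as.numeric(positions),
                 n = nrow(G), m = ncol(G)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (MAF %.2g-%.2g)\n",
              x$n, x$m, min(x$maf), max(x$maf)))
  invisible(x)
}

#' Subset the variants of a genotype matrix
#' @param gm A \code{genotype_matrix}.
#' @param idx Variant indices to keep.
#' @return A \code{genotype_matrix} restricted to \code{idx}.
#' @export
subset_variants <- function(gm, idx) {
  stopifnot(inherits(gm, "genotype_matrix"))
  new_genotype_matrix(gm$G[, idx, drop = FALSE], gm$maf[idx], gm$positions[idx])
}

#' Write / read a haplotype pool as plain text
#'
#' The export format is a whitespace-delimited 0/1 matrix, one haplotype per
#' row, accompanied by a positions file (one bp coordinate per line, first
#' line the span). Intended for importing pools produced by external
#' coalescent simulators.
#'
#' @param pool A haplotype pool.
#' @param alleles_file,positions_file Output/input paths.
#' @return \code{read_haplotype_pool} returns a \code{haplotype_pool};
#'   \code{write_haplotype_pool} returns the alleles path invisibly.
#' @export
write_haplotype_pool <- function(pool, alleles_file, positions_file) {
  A <- as.matrix(pool$alleles)
  utils::write.table(A, alleles_file, row.names = FALSE, col.names = FALSE)
  writeLines(c(format(pool$span, scientific = FALSE),
               format(pool$positions, scientific = FALSE)), positions_file)
  invisible(alleles_file)
}

#' @rdname write_haplotype_pool
#' @export
read_haplotype_pool <- function(alleles_file, positions_file) {
  A <- as.matrix(utils::read.table(alleles_file, header = FALSE))
  dimnames(A) <- NULL
  pos_lines <- readLines(positions_file)
  span <- as.numeric(pos_lines[1])
  positions <- as.numeric(pos_lines[-1])
  if (length(positions) != ncol(A))
    stop("positions file does not match allele matrix", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  counts <- colSums(A)
  if (any(counts == 0 | counts == nrow(A)))
    stop("monomorphic sites are not allowed in a pool", call. = FALSE)
  new_haplotype_pool(Matrix::Matrix(A, sparse = TRUE), positions, span)
}

## Seed scoping: run a block under a given seed, restoring the caller's RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
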