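# omics module: CPM normalization, replicate QC, translational efficiency,
# and rank-based pathway prioritization.

#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' Assemble a count matrix with assay and replicate metadata
#'
#' Counts are stored in a [SummarizedExperiment::SummarizedExperiment] with
#' one `counts` assay; `colData` carries the sequencing assay (`"rna"` or
#' `"ribo"`) and replicate index of each sample. Sample names follow the
#' `assay_replicate` convention (`rna_1`, `ribo_3`, ...).
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids.
#' @param assay character vector (`"rna"`/`"ribo"`) per sample.
#' @param replicate integer replicate index per sample.
#' @return A `SummarizedExperiment` with a `counts` assay.
#' @examples
#' cm <- countMatrix(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3))),
#'                   assay = c("rna", "rna"), replicate = 1:2)
#' SummarizedExperiment::colData(cm)
#' @export
countMatrix <- function(counts, assay, replicate) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must have gene ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene ids in counts", call. = FALSE)
  }
  if (length(assay) != ncol(counts) || length(replicate) != ncol(counts)) {
    stop("assay and replicate metadata must cover every sample",
         call. = FALSE)
  }
  if (!all(assay %in% c("rna", "ribo"))) {
    stop("assay must be 'rna' or 'ribo'", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts)) || anyNA(counts)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  colnames(counts) <- paste0(assay, "_", replicate)
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(assay = as.character(assay),
                        replicate = as.integer(replicate),
                        row.names = colnames(counts)))
}

.assayMatrix <- function(x, what) {
  if (!is(x, "SummarizedExperiment")) {
    stop("expected a SummarizedExperiment, got ", class(x)[1], call. = FALSE)
  }
  if (!what %in% assayNames(x)) {
    stop("object has no '", what, "' assay (assays: ",
         paste(assayNames(x), collapse = ", "), ")", call. = FALSE)
  }
  assay(x, what)
}

#' Counts-per-million normalization
#'
#' CPM of gene g in sample s is its raw count divided by the sample's total
#' raw counts, times 1e6; every normalized column therefore sums to 1e6.
#'
#' @param counts a `SummarizedExperiment` with a `counts` assay (from
#'   [countMatrix()], [loadCounts()] or [simulateCounts()]).
#' @return A `SummarizedExperiment` with a `cpm` assay and the same
#'   `colData`.
#' @examples
#' cm <- countMatrix(matrix(c(1, 1, 2), 3, 1,
#'                          dimnames = list(paste0("g", 1:3))),
#'                   assay = "rna", replicate = 1)
#' SummarizedExperiment::assay(cpmNormalize(cm), "cpm")
#' @export
cpmNormalize <- function(counts) {
  m <- .assayMatrix(counts, "counts")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(m, 2, totals, "/") * 1e6
  SummarizedExperiment(assays = list(cpm = cpm), colData = colData(counts))
}

#' Replicate quality control
#'
#' Within each assay, computes the Pearson correlation and a two-tailed
#' Welch t-test for every pair of replicates on `log10(CPM + 1)` values.
#' QC passes when all pairwise correlations exceed `pccFloor` and no
#' t-test rejects at `alpha`: replicates should look like the same
#' distribution, strongly correlated gene by gene.
#'
#' @param cpm a `SummarizedExperiment` with a `cpm` assay.
#' @param pccFloor minimum acceptable pairwise Pearson correlation
#'   (default 0.9).
#' @param alpha significance level for the t-tests (default 0.05).
#' @return list with components `pcc` and `ttestP` (per-assay symmetric
#'   matrices), `pass`, and `untested` (`TRUE` when an assay has a single
#'   replicate, in which case QC is skipped with a warning).
#' @export
replicateQC <- function(cpm, pccFloor = 0.9, alpha = 0.05) {
  stopifnot(pccFloor > 0, pccFloor < 1, alpha > 0, alpha < 1)
  m <- log10(.assayMatrix(cpm, "cpm") + 1)
  meta <- colData(cpm)
  pcc <- list()
  tp <- list()
  pass <- TRUE
  untested <- FALSE
  for (a in unique(meta$assay)) {
    cols <- which(meta$assay == a)
    k <- length(cols)
    if (k < 2L) {
      warning("assay '", a, "' has a single replicate; QC untested")
      untested <- TRUE
      next
    }
    cc <- matrix(1, k, k, dimnames = list(colnames(m)[cols],
                                          colnames(m)[cols]))
    pp <- matrix(1, k, k, dimnames = dimnames(cc))
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cc[i, j] <- cc[j, i] <- cor(m[, cols[i]], m[, cols[j]])
        pp[i, j] <- pp[j, i] <- t.test(m[, cols[i]], m[, cols[j]],
                                       var.equal = FALSE)$p.value
      }
    }
    pcc[[a]] <- cc
    tp[[a]] <- pp
    off <- upper.tri(cc)
    pass <- pass && all(cc[off] > pccFloor) && all(pp[off] >= alpha)
  }
  list(pcc = pcc, ttestP = tp, pass = pass, untested = untested)
}

#' Gene-level translational efficiency
#'
#' TE of a gene is its replicate-mean Ribo-Seq CPM divided by its
#' replicate-mean RNA-Seq CPM. Genes whose mean RNA CPM does not exceed
#' `minCpm` (default 0, i.e. only zero-expression genes) are flagged
#' `included = FALSE` and receive no TE -- there is no pseudocount, so a
#' zero denominator is excluded rather than inflated.
#'
#' @param rna,ribo `SummarizedExperiment`s with a `cpm` assay over an
#'   identical gene universe.
#' @param minCpm inclusion floor on mean RNA CPM.
#' @return data.frame with columns `gene`, `rna_cpm`, `ribo_cpm`, `te`,
#'   `included`.
#' @export
geneTE <- function(rna, ribo, minCpm = 0) {
  mr <- .assayMatrix(rna, "cpm")
  mb <- .assayMatrix(ribo, "cpm")
  if (!identical(sort(rownames(mr)), sort(rownames(mb)))) {
    d <- c(setdiff(rownames(mr), rownames(mb)),
           setdiff(rownames(mb), rownames(mr)))
    stop("gene universes differ between rna and ribo: ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  mb <- mb[rownames(mr), , drop = FALSE]
  meanR <- rowMeans(mr)
  meanB <- rowMeans(mb)
  included <- meanR > minCpm
  te <- ifelse(included, meanB / meanR, NA_real_)
  data.frame(gene = rownames(mr), rna_cpm = meanR, ribo_cpm = meanB,
             te = te, included = included, row.names = NULL,
             stringsAsFactors = FALSE)
}

# One-tailed Mann-Whitney U via stats::wilcox.test: exact when the
# combined sample is small and tie-free, normal approximation with tie and
# continuity correction otherwise.
.mwu <- function(x, y, alternative) {
  exact <- (length(x) + length(y)) <= 25 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

.asPathwayList <- function(pathways) {
  if (is.data.frame(pathways)) {
    stopifnot(ncol(pathways) >= 2L)
    return(split(as.character(pathways[[1]]), as.character(pathways[[2]])))
  }
  if (is.list(pathways)) {
    if (is.null(names(pathways))) {
      stop("pathway list must be named", call. = FALSE)
    }
    return(lapply(pathways, as.character))
  }
  stop("pathways must be a named list or a two-column data.frame",
       call. = FALSE)
}

#' Pathway-level translational prioritization
#'
#' All included genes are ranked by replicate-mean CPM separately within
#' the RNA-Seq and the Ribo-Seq datasets (average ranks on ties). For each
#' pathway, a right- and a left-tailed Mann-Whitney U test compares the
#' Ribo ranks of its genes against the RNA ranks of the same genes: a
#' pathway whose genes sit systematically higher in the translatome than
#' in the transcriptome ranks is translationally prioritized. A pathway is
#' classified `"up"` when its mean TE is at least 1 and the right-tailed p
#' is below `alpha`, `"down"` when mean TE is at most 1 and the
#' left-tailed p is below `alpha`, and `"ns"` otherwise. Raw p-values
#' drive the classification; Benjamini-Hochberg-adjusted columns are
#' appended for reference.
#'
#' @param te TE table from [geneTE()].
#' @param rna,ribo the CPM `SummarizedExperiment`s used for `te`.
#' @param pathways named list of gene-id vectors, or a two-column
#'   data.frame (gene, pathway). Genes mapped to several pathways
#'   contribute to each.
#' @param alpha significance level (default 0.05).
#' @param minGenes minimum number of included genes for a pathway to be
#'   testable (default 3); smaller pathways are reported as `"ns"` with
#'   `insufficient = TRUE`, never dropped.
#' @return data.frame with one row per pathway: `pathway`, `n_genes`,
#'   `mean_te`, `U`, `p_right`, `p_left`, `class`, `insufficient`,
#'   `p_right_bh`, `p_left_bh`.
#' @export
pathwayPrioritization <- function(te, rna, ribo, pathways, alpha = 0.05,
                                  minGenes = 3L) {
  stopifnot(alpha > 0, alpha < 1, minGenes >= 2L)
  pw <- .asPathwayList(pathways)
  unknown <- setdiff(unique(unlist(pw)), te$gene)
  if (length(unknown)) {
    stop("pathways reference genes absent from the TE table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  inc <- te$gene[te$included]
  mr <- rowMeans(.assayMatrix(rna, "cpm"))[inc]
  mb <- rowMeans(.assayMatrix(ribo, "cpm"))[inc]
  rnaRank <- rank(mr)
  riboRank <- rank(mb)
  tev <- setNames(te$te, te$gene)
  out <- lapply(names(pw), function(pn) {
    gs <- intersect(pw[[pn]], inc)
    n <- length(gs)
    meanTe <- if (n) mean(tev[gs]) else NA_real_
    if (n < minGenes) {
      return(data.frame(pathway = pn, n_genes = n, mean_te = meanTe,
                        U = NA_real_, p_right = NA_real_, p_left = NA_real_,
                        class = "ns", insufficient = TRUE,
                        stringsAsFactors = FALSE))
    }
    right <- .mwu(riboRank[gs], rnaRank[gs], "greater")
    left <- .mwu(riboRank[gs], rnaRank[gs], "less")
    cls <- if (meanTe >= 1 && right$p < alpha) "up"
      else if (meanTe <= 1 && left$p < alpha) "down"
      else "ns"
    data.frame(pathway = pn, n_genes = n, mean_te = meanTe, U = right$U,
               p_right = right$p, p_left = left$p, class = cls,
               insufficient = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_right_bh <- p.adjust(res$p_right, method = "BH")
  res$p_left_bh <- p.adjust(res$p_left, method = "BH")
  rownames(res) <- NULL
  res
}
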