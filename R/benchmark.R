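# benchmark module: subsystem aggregation, log transform, regression and
# Pearson correlation between model flux profiles and omics signal.

.asMappingFrame <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    out <- data.frame(id = as.character(mapping[[1]]),
                      subsystem = as.character(mapping[[2]]),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.character(mapping) && !is.null(names(mapping))) {
    return(data.frame(id = names(mapping), subsystem = unname(mapping),
                      stringsAsFactors = FALSE))
  }
  stop("mapping must be a two-column data.frame (id, subsystem) or a ",
       "named character vector", call. = FALSE)
}

#' Aggregate values to subsystem level
#'
#' Sums absolute values (reaction fluxes, translation fluxes or CPM) over
#' each annotated subsystem and applies the `log10(f + 1)` transform.
#' Absolute values are summed so that opposing fluxes within a subsystem
#' cannot cancel. Ids without a subsystem annotation are collected in the
#' `unmapped` report, never silently dropped; an id annotated to several
#' subsystems contributes to each.
#'
#' @param values named numeric vector (one value per reaction or gene), or
#'   a named-row matrix with one column per sample, in which case each
#'   column is aggregated and the profile is stacked with a `sample`
#'   column.
#' @param mapping two-column data.frame (id, subsystem) or named character
#'   vector.
#' @param mode one of `"cpm"`, `"reaction_flux"`, `"translation_flux"`
#'   (recorded in the result; the arithmetic is identical).
#' @return list with `profile` (data.frame: `subsystem`, optional
#'   `sample`, `f`, `log_f`), `unmapped` (character) and `mode`.
#' @examples
#' aggregateSubsystem(c(gA = 100, gB = 200),
#'                    data.frame(id = c("gA", "gB"),
#'                               subsystem = c("S1", "S1")))$profile
#' @export
aggregateSubsystem <- function(values,
                               mapping,
                               mode = c("cpm", "reaction_flux",
                                        "translation_flux")) {
  mode <- match.arg(mode)
  map <- .asMappingFrame(mapping)
  if (!nrow(map)) stop("empty subsystem mapping", call. = FALSE)
  one <- function(v, sample = NULL) {
    ids <- names(v)
    if (is.null(ids)) stop("values must be named", call. = FALSE)
    hit <- map[map$id %in% ids, , drop = FALSE]
    f <- tapply(abs(v[hit$id]), hit$subsystem, sum)
    out <- data.frame(subsystem = names(f), f = as.numeric(f),
                      stringsAsFactors = FALSE)
    if (!is.null(sample)) out$sample <- sample
    out
  }
  if (is.matrix(values)) {
    prof <- do.call(rbind, lapply(colnames(values), function(s) {
      one(setNames(values[, s], rownames(values)), sample = s)
    }))
    unmapped <- setdiff(rownames(values), map$id)
  } else {
    prof <- one(values)
    unmapped <- setdiff(names(values), map$id)
  }
  prof$log_f <- log10(prof$f + 1)
  rownames(prof) <- NULL
  list(profile = prof, unmapped = unmapped, mode = mode)
}

.asProfileFrame <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$profile)) {
    return(x$profile)
  }
  if (is.data.frame(x)) return(x)
  stop("expected a subsystem profile (from aggregateSubsystem) or a ",
       "data.frame", call. = FALSE)
}

#' Correlate two subsystem profiles
#'
#' Ordinary least squares of `y` on `x` and the Pearson correlation, both
#' on the `log10(f + 1)` scale, over the subsystems present in both
#' profiles. When one side carries several samples per subsystem (a
#' stacked omics profile), every sample row is paired with the other
#' side's value for that subsystem, so all samples enter the regression.
#' Subsystems present on only one side are excluded and reported.
#'
#' Note the asymmetry: the regression of y on x is not the regression of
#' x on y, while the Pearson correlation is symmetric.
#'
#' @param x,y results of [aggregateSubsystem()] (or bare profile
#'   data.frames). `x` is the predictor (model side by convention).
#' @return list with `n`, `slope`, `intercept`, `ci` (2x2 matrix of 95%
#'   confidence limits), `pcc`, `p`, `pairs` (merged data.frame) and
#'   `excluded` (subsystems missing from either side).
#' @examples
#' p <- aggregateSubsystem(c(a = 1, b = 10, c = 100),
#'                         data.frame(id = letters[1:3],
#'                                    subsystem = LETTERS[1:3]))
#' r <- correlateProfiles(p, p)
#' c(r$slope, r$pcc)
#' @export
correlateProfiles <- function(x, y) {
  px <- .asProfileFrame(x)
  py <- .asProfileFrame(y)
  shared <- intersect(px$subsystem, py$subsystem)
  excluded <- union(setdiff(px$subsystem, shared),
                    setdiff(py$subsystem, shared))
  if (length(shared) < 3L) {
    stop("need at least 3 shared subsystems, got ", length(shared),
         call. = FALSE)
  }
  kx <- px[px$subsystem %in% shared, c("subsystem", "log_f")]
  ky <- py[py$subsystem %in% shared, c("subsystem", "log_f")]
  names(kx)[2] <- "x"
  names(ky)[2] <- "y"
  pairs <- merge(kx, ky, by = "subsystem")
  fit <- lm(y ~ x, data = pairs)
  ct <- suppressWarnings(cor.test(pairs$x, pairs$y, method = "pearson"))
  list(n = nrow(pairs),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       # confint warns about "essentially perfect fit" on degenerate
       # inputs (e.g. self-benchmarks); the interval is still what we want
       ci = suppressWarnings(confint(fit, level = 0.95)),
       pcc = unname(ct$estimate),
       p = ct$p.value,
       pairs = pairs,
       excluded = excluded)
}
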