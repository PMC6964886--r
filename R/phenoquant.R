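# Phenotype quantification formulas: stomatal index and density from
# epidermal counts, delta-delta-Ct relative expression from qRT-PCR Ct
# tables, and firefly/Renilla dual-luciferase normalization.

#' Stomatal index
#'
#' The percentage of epidermal cells that are stomata:
#' \code{100 * stomata / (stomata + epidermalCells)}.
#'
#' @param stomata integer count(s) of stomata in the counting region,
#'   >= 0.
#' @param epidermalCells integer count(s) of non-stomatal epidermal
#'   cells, >= 0.  Each \code{stomata + epidermalCells} must be >= 1.
#' @return Stomatal index in percent, in [0, 100]; vectorized.
#' @examples
#' stomatalIndex(10, 40)   # 20
#' @export
stomatalIndex <- function(stomata, epidermalCells) {
  checkCounts(stomata, "stomata")
  checkCounts(epidermalCells, "epidermalCells")
  tot <- stomata + epidermalCells
  if (any(tot < 1))
    stopInput("stomatal index undefined: stomata + epidermalCells must be >= 1")
  100 * stomata / tot
}

#' Stomatal density
#'
#' Stomata per square millimetre of leaf surface.  A typical counting
#' region of 400 um x 400 um has an area of 0.16 mm^2.
#'
#' @param stomata integer count(s) of stomata, >= 0.
#' @param roiAreaMm2 counting-region area(s) in mm^2, > 0.
#' @return Density in stomata per mm^2; vectorized.
#' @examples
#' stomatalDensity(24, 0.16)   # 150 per mm^2
#' @export
stomatalDensity <- function(stomata, roiAreaMm2) {
  checkCounts(stomata, "stomata")
  if (any(!is.finite(roiAreaMm2)) || any(roiAreaMm2 <= 0))
    stopInput("roiAreaMm2 must be strictly positive")
  stomata / roiAreaMm2
}

checkCounts <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
    stopInput("'%s' must be non-negative integer counts", name)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, \code{dCt = Ct_target - Ct_reference} (reference
#' measurements of the same sample are averaged if replicated); per
#' (gene, condition), dCt is averaged over replicate samples; then
#' \code{ddCt = dCt_condition - dCt_calibrator} and relative expression is
#' \code{2^-ddCt}, assuming the classic amplification efficiency of 2.
#' The calibrator condition maps to exactly 1 by construction.
#'
#' Replicates are aggregated as the arithmetic mean of dCt within a
#' condition before the delta-delta step (not as a mean of fold-changes);
#' users preferring the other convention should aggregate externally.
#'
#' @param ct a \code{data.frame} with columns \code{sample_id},
#'   \code{condition}, \code{gene}, \code{ct}, \code{reference_gene}.
#'   Rows where \code{gene == reference_gene} are the normalizer
#'   measurements; every (sample, target gene) needs a same-sample row
#'   for its reference gene.
#' @param calibrator the condition all expression is relative to.
#' @return A \code{data.frame} with one row per (gene, condition):
#'   \code{gene}, \code{condition}, \code{n} (replicate samples),
#'   \code{delta_ct}, \code{delta_delta_ct}, \code{relative_expression}.
#' @examples
#' ct <- data.frame(
#'   sample_id = c("a", "a", "b", "b"),
#'   condition = c("treated", "treated", "control", "control"),
#'   gene = c("TARGET", "UBC21", "TARGET", "UBC21"),
#'   ct = c(25, 20, 24, 20),
#'   reference_gene = "UBC21")
#' relativeExpression(ct, calibrator = "control")
#' @export
relativeExpression <- function(ct, calibrator) {
  need <- c("sample_id", "condition", "gene", "ct", "reference_gene")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stopInput("Ct table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stopInput("Ct values must be finite and > 0")
  if (!calibrator %in% ct$condition)
    stopInput("calibrator condition '%s' not present in the Ct table",
              calibrator)
  targets <- ct[ct$gene != ct$reference_gene, , drop = FALSE]
  if (nrow(targets) == 0L)
    stopInput("Ct table contains no target-gene measurements")
  refs <- ct[ct$gene == ct$reference_gene, , drop = FALSE]
  refKey <- paste(refs$sample_id, refs$gene, sep = "\r")
  dct <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    key <- paste(targets$sample_id[i], targets$reference_gene[i], sep = "\r")
    hit <- refKey == key
    if (!any(hit))
      stopInput("missing reference-gene measurement: sample '%s', gene '%s' has no %s Ct",
                targets$sample_id[i], targets$gene[i],
                targets$reference_gene[i])
    dct[i] <- targets$ct[i] - mean(refs$ct[hit])
  }
  agg <- stats::aggregate(dct,
                          by = list(gene = targets$gene,
                                    condition = targets$condition),
                          FUN = mean)
  names(agg)[3L] <- "delta_ct"
  nrep <- stats::aggregate(dct,
                           by = list(gene = targets$gene,
                                     condition = targets$condition),
                           FUN = length)[[3L]]
  agg$n <- as.integer(nrep)
  out <- do.call(rbind, lapply(split(agg, agg$gene), function(g) {
    cal <- g$delta_ct[g$condition == calibrator]
    if (length(cal) != 1L)
      stopInput("gene '%s' has no measurement in calibrator condition '%s'",
                g$gene[1L], calibrator)
    g$delta_delta_ct <- g$delta_ct - cal
    g$relative_expression <- 2^(-g$delta_delta_ct)
    g
  }))
  rownames(out) <- NULL
  out <- out[order(out$gene, out$condition),
             c("gene", "condition", "n", "delta_ct", "delta_delta_ct",
               "relative_expression")]
  rownames(out) <- NULL
  out
}

#' Dual-luciferase normalized reporter activity
#'
#' Firefly luciferase luminescence divided by the co-transfected Renilla
#' luminescence, controlling for transfection efficiency.  The ratio is
#' invariant under instrument gain (scaling both readings).
#'
#' @param firefly firefly luminescence, >= 0; vectorized.
#' @param renilla Renilla luminescence, > 0.
#' @return \code{firefly / renilla}.
#' @examples
#' luciferaseRatio(1000, 500)   # 2
#' @export
luciferaseRatio <- function(firefly, renilla) {
  if (any(!is.finite(firefly)) || any(firefly < 0))
    stopInput("firefly luminescence must be finite and >= 0")
  if (any(!is.finite(renilla)) || any(renilla <= 0))
    stopInput("no transfection-control signal: renilla luminescence must be > 0")
  firefly / renilla
}

#' Compare measurements between conditions (thin wrapper)
#'
#' A convenience pass-through to the standard routines used for this kind
#' of data: Welch's t-test for two groups, one-way ANOVA with Tukey HSD
#' for more.  No statistics are re-implemented here.
#'
#' @param values numeric measurements.
#' @param groups grouping factor of the same length.
#' @param method \code{"welch"} or \code{"anova"}.
#' @return The object returned by \code{stats::t.test}, or a list with
#'   the \code{stats::aov} fit and its \code{TukeyHSD}.
#' @export
compareConditions <- function(values, groups, method = c("welch", "anova")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (method == "welch") {
    if (nlevels(groups) != 2L)
      stopInput("Welch's t-test needs exactly two groups")
    stats::t.test(values ~ groups)
  } else {
    fit <- stats::aov(values ~ groups)
    list(aov = fit, tukey = stats::TukeyHSD(fit))
  }
}

# ---- tabular CSV readers ----------------------------------------------

readTable <- function(path, need, what) {
  if (!file.exists(path)) stopIO("file not found: '%s'", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopIO("cannot read CSV '%s': %s",
                                            path, conditionMessage(e)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopInput("%s table '%s' is missing column(s): %s", what, path,
              paste(miss, collapse = ", "))
  df
}

#' Read tabular phenotype records from CSV
#'
#' \code{readCountTable}: stomatal count records with columns
#' \code{sample_id, stomata, epidermal_cells, roi_area_mm2}.
#' \code{readCtTable}: qRT-PCR Ct records with columns
#' \code{sample_id, condition, gene, ct, reference_gene}.
#' \code{readLucTable}: dual-luciferase records with columns
#' \code{sample_id, firefly, renilla}.
#'
#' @param path CSV file path.
#' @return A validated \code{data.frame}.
#' @export
readCountTable <- function(path) {
  df <- readTable(path, c("sample_id", "stomata", "epidermal_cells",
                          "roi_area_mm2"), "count")
  checkCounts(df$stomata, "stomata")
  checkCounts(df$epidermal_cells, "epidermal_cells")
  if (any(df$roi_area_mm2 <= 0))
    stopInput("count table '%s': roi_area_mm2 must be > 0", path)
  df
}

#' @rdname readCountTable
#' @export
readCtTable <- function(path) {
  readTable(path, c("sample_id", "condition", "gene", "ct",
                    "reference_gene"), "Ct")
}

#' @rdname readCountTable
#' @export
readLucTable <- function(path) {
  df <- readTable(path, c("sample_id", "firefly", "renilla"), "luciferase")
  if (any(df$renilla <= 0))
    stopInput("luciferase table '%s': renilla must be > 0", path)
  df
}
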