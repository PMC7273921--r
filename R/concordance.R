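# Per-patient study table, three-way concordance classification and the
# agreement statistics used to compare imaging localizations with the
# clinical reference standard.

concordanceLevels <- c("concordant", "partially_concordant", "discordant")

#' Read a per-patient study table
#'
#' Reads a tab-separated table with columns `patient_id`, `ez_side`
#' (left/right/bilateral), `ez_lobes` (one or more lobe names separated by
#' `;`; more than one marks multifocal epilepsy), `injection_time_s` (seconds
#' from seizure onset to radiotracer injection; `NA` when unrecorded),
#' `visual_label` and `siscom_label` (concordant / partially_concordant /
#' discordant vs. the reference standard), `operated` (TRUE/FALSE) and
#' `engel` (surgical outcome class, `NA` when not operated).
#'
#' @param path path to the TSV file.
#' @return A validated data.frame with one row per patient and a list column
#'   `ez_lobes`.
#' @seealso [studyTableFixture()]
#' @export
readStudyTable <- function(path) {
  t <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("patient_id", "ez_side", "ez_lobes", "injection_time_s",
            "visual_label", "siscom_label", "operated", "engel")
  missing <- setdiff(need, names(t))
  if (length(missing))
    stop("study table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(t$patient_id)) stop("patient_id values must be unique")
  t$ez_lobes <- strsplit(t$ez_lobes, ";", fixed = TRUE)
  if (any(lengths(t$ez_lobes) < 1L)) stop("ez_lobes must be non-empty")
  if (any(!t$ez_side %in% c("left", "right", "bilateral")))
    stop("ez_side must be left, right or bilateral")
  for (col in c("visual_label", "siscom_label"))
    if (any(!t[[col]] %in% concordanceLevels))
      stop(col, " must be one of: ", paste(concordanceLevels, collapse = ", "))
  if (any(!is.na(t$injection_time_s) & t$injection_time_s <= 0))
    stop("injection_time_s must be > 0 when present")
  t
}

#' The packaged 23-patient study table
#'
#' The per-patient fixture shipped with the package: reference-standard EZ
#' side and lobe(s), radiotracer injection time (one patient unrecorded),
#' the visual-analysis and subtraction-analysis concordance labels, and
#' surgical status/outcome where available. It is data, never regenerated.
#'
#' @return The table as returned by [readStudyTable()] (23 rows).
#' @export
studyTableFixture <- function() {
  path <- system.file("extdata", "study_table_23pt.tsv", package = "siscom",
                      mustWork = TRUE)
  t <- readStudyTable(path)
  if (nrow(t) != 23L) stop("packaged fixture must have exactly 23 records")
  t
}

#' Classify an imaging localization against the reference standard
#'
#' Both arguments are sets of (side, lobe) pairs. The call is `concordant`
#' when the predicted set covers every reference pair (overlap with the full
#' EZ), `partially_concordant` when it covers some but not all pairs of a
#' multifocal reference, and `discordant` when the predicted set is empty or
#' shares no pair with the reference (no hyperperfusion seen, or
#' hyperperfusion in a different lobe).
#'
#' @param predicted character vector of `"side:lobe"` pairs (possibly empty).
#' @param reference non-empty character vector of `"side:lobe"` pairs.
#' @return One of `"concordant"`, `"partially_concordant"`, `"discordant"`.
#' @examples
#' classifyConcordance("left:temporal", "left:temporal")
#' classifyConcordance("right:frontal", c("right:frontal", "right:occipital"))
#' classifyConcordance("left:frontal", "left:temporal")
#' @export
classifyConcordance <- function(predicted, reference) {
  if (!length(reference)) stop("reference must be non-empty")
  norm <- function(x) unique(tolower(trimws(x)))
  p <- norm(predicted[nzchar(predicted)])
  r <- norm(reference)
  hit <- r %in% p
  if (all(hit)) "concordant"
  else if (any(hit)) "partially_concordant"
  else "discordant"
}

# half-up rounding (round() in R rounds half to even)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentages at 1 decimal constrained to sum to 100 (largest-remainder);
# reproduces how per-category percentages are conventionally printed
pctLargestRemainder <- function(counts, digits = 1) {
  p <- 10^digits
  raw <- 100 * counts / sum(counts)
  fl <- floor(raw * p) / p
  need <- as.integer(round((100 - sum(fl)) * p))
  add <- rep(0, length(counts))
  if (need > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    add[ord[seq_len(need)]] <- 1 / p
  }
  fl + add
}

#' Summarize concordance labels for one method
#'
#' Counts each concordance label for the chosen analysis method and reports
#' percentages of the total at one decimal. `pct` uses largest-remainder
#' rounding so the three percentages sum to 100.0 (the convention behind the
#' printed study percentages); `pct_raw` is plain half-up rounding.
#'
#' @param table a study table from [readStudyTable()].
#' @param method `"siscom"` or `"visual"`.
#' @return data.frame with columns `label`, `n`, `pct`, `pct_raw`.
#' @examples
#' summarizeTable(studyTableFixture(), "siscom")
#' @export
summarizeTable <- function(table, method = c("siscom", "visual")) {
  method <- match.arg(method)
  if (!nrow(table)) stop("empty study table")
  col <- paste0(method, "_label")
  counts <- vapply(concordanceLevels,
                   function(l) sum(table[[col]] == l), integer(1))
  data.frame(label = concordanceLevels,
             n = as.integer(counts),
             pct = pctLargestRemainder(counts),
             pct_raw = roundHalfUp(100 * counts / sum(counts), 1),
             row.names = NULL)
}

#' Cohen's kappa for two paired label vectors
#'
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' marginal products. The degenerate case p_e = 1 (both raters constant)
#' returns 1 when observed agreement is perfect and errors otherwise.
#'
#' @param labelsA,labelsB equal-length vectors over a shared category set.
#' @return kappa in \[-1, 1\].
#' @examples
#' cohenKappa(rep(c("a", "b"), c(25, 25)),
#'            rep(c("a", "b", "a", "b"), c(20, 5, 10, 15)))
#' @export
cohenKappa <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  if (!length(labelsA)) stop("label vectors must be non-empty")
  lev <- sort(unique(c(as.character(labelsA), as.character(labelsB))))
  a <- factor(labelsA, levels = lev)
  b <- factor(labelsB, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    stop("expected agreement is 1 with imperfect observed agreement")
  }
  (po - pe) / (1 - pe)
}

#' McNemar test from discordant-pair counts
#'
#' `b` and `c` are the two off-diagonal counts of the paired 2x2 table.
#' `exact` is the two-sided binomial test with success probability 1/2 on
#' b + c trials (p capped at 1); `chi2` is (b - c)^2 / (b + c); `chi2_cc`
#' applies the continuity correction (|b - c| - 1)^2 / (b + c).
#'
#' @param b,c non-negative discordant counts.
#' @param mode `"exact"`, `"chi2"` or `"chi2_cc"`.
#' @return list with `statistic` (NA for exact) and `p.value`.
#' @examples
#' mcnemarTest(7, 2, "exact")$p.value  # 92/512
#' @export
mcnemarTest <- function(b, c, mode = c("exact", "chi2", "chi2_cc")) {
  mode <- match.arg(mode)
  if (b < 0 || c < 0) stop("counts must be >= 0")
  n <- b + c
  if (mode == "exact") {
    p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    return(list(statistic = NA_real_, p.value = p))
  }
  if (n == 0) stop("b + c must be > 0 for chi-square modes")
  stat <- if (mode == "chi2") (b - c)^2 / n else (abs(b - c) - 1)^2 / n
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# the three standard ways to dichotomize a partially-concordant label before
# a paired 2x2 test; how the study did it is not recoverable, so all three
# are computed and labelled explicitly
dichotomizeLabels <- function(labels, rule = c("partial_as_concordant",
                                               "partial_as_discordant",
                                               "partial_excluded")) {
  rule <- match.arg(rule)
  out <- labels
  if (rule == "partial_as_concordant")
    out[out == "partially_concordant"] <- "concordant"
  else if (rule == "partial_as_discordant")
    out[out == "partially_concordant"] <- "discordant"
  else out[out == "partially_concordant"] <- NA_character_
  out
}

#' McNemar comparison of two methods' concordance labels
#'
#' Dichotomizes the three-way labels under each of the three explicit rules
#' for partially-concordant cases, forms the paired 2x2 table of
#' concordant-vs-not between the two methods, and runs [mcnemarTest()].
#'
#' @param table a study table.
#' @param mode test variant passed to [mcnemarTest()].
#' @return data.frame with one row per dichotomization rule: rule, b (first
#'   method concordant only), c (second only), statistic, p.value.
#' @export
compareMethodsMcnemar <- function(table, mode = "exact") {
  rules <- c("partial_as_concordant", "partial_as_discordant",
             "partial_excluded")
  rows <- lapply(rules, function(rule) {
    va <- dichotomizeLabels(table$visual_label, rule)
    sa <- dichotomizeLabels(table$siscom_label, rule)
    keep <- !is.na(va) & !is.na(sa)
    b <- sum(va[keep] != "concordant" & sa[keep] == "concordant")
    c2 <- sum(va[keep] == "concordant" & sa[keep] != "concordant")
    res <- mcnemarTest(b, c2, mode)
    data.frame(rule = rule, b = b, c = c2, statistic = res$statistic,
               p.value = res$p.value)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. The p-value is exact for combined
#' sample size <= 12 without ties, and otherwise uses the normal
#' approximation with tie-corrected variance (and continuity correction).
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` and two-sided `p.value`.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- (length(x) + length(y)) <= 12L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = useExact, correct = TRUE))
  list(U = unname(res$statistic), p.value = res$p.value)
}

#' Descriptive summary with missing values excluded
#'
#' @param values numeric vector, possibly with NAs; at least two non-missing
#'   values are required for the SD.
#' @return list with `n`, `nMissing`, `mean`, `sd` (sample, n - 1), `min`,
#'   `max`, plus `mean1`/`sd1` rounded half-up at one decimal for reporting.
#' @examples
#' summaryStats(c(2, 2, 2))
#' @export
summaryStats <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values are missing")
  if (length(v) < 2L) stop("need at least 2 non-missing values for the SD")
  list(n = length(v), nMissing = sum(is.na(values)),
       mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
       mean1 = roundHalfUp(mean(v), 1), sd1 = roundHalfUp(stats::sd(v), 1))
}
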