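#' Build the gene x patient 2x2 event table
#'
#' Every (panel gene, patient) pair contributes one binary detection event
#' from the patient's diagnosis-plasma sample(s): `a`/`b` are the detected/
#' undetected events among patients who later relapsed, `c`/`d` among those
#' who did not. Panel genes absent from the matrix count as undetected.
#'
#' @param panel_genes Character vector of panel genes (or a
#'   `signature_panel`).
#' @param pm Diagnosis-plasma [presence_matrix()] (other strata are ignored).
#' @param labels Named vector mapping `patient_id` to `"relapse"` /
#'   `"no_relapse"`; when `NULL`, taken from the matrix's `later_relapse`
#'   metadata (`yes`/`no`).
#' @param allow_unknown Drop unlabeled patients with a warning instead of
#'   failing.
#' @return An `event_table_2x2` list with cells `a`, `b`, `c`, `d` and the
#'   group compositions.
#' @export
build_event_table <- function(panel_genes, pm, labels = NULL,
                              allow_unknown = FALSE) {
  if (inherits(panel_genes, "signature_panel")) panel_genes <- panel_genes$genes
  stopifnot(length(panel_genes) > 0)
  sub <- pm_subset(pm, stage = "diagnosis", tissue = "plasma")
  if (ncol(sub$detected) == 0) stop("no diagnosis-plasma samples in matrix")
  if (is.null(labels)) {
    labels <- c(yes = "relapse", no = "no_relapse",
                unknown = NA_character_)[sub$samples$later_relapse]
    names(labels) <- sub$samples$patient_id
    labels <- labels[!duplicated(names(labels))]
  }
  patients <- unique(sub$samples$patient_id)
  lab <- labels[patients]
  if (anyNA(lab) || any(!lab %in% c("relapse", "no_relapse"))) {
    bad <- patients[is.na(lab) | !lab %in% c("relapse", "no_relapse")]
    if (!allow_unknown) stop("unlabeled patient(s): ", paste(bad, collapse = ", "))
    warning("dropping unlabeled patient(s): ", paste(bad, collapse = ", "))
    patients <- setdiff(patients, bad)
    lab <- labels[patients]
  }
  det <- vapply(patients, function(p) {
    cols <- sub$samples$sample_id[sub$samples$patient_id == p]
    m <- sub$detected[intersect(panel_genes, rownames(sub$detected)), cols,
                      drop = FALSE]
    found <- rowSums(m) > 0
    sum(found)  # genes detected for this patient (missing genes = 0)
  }, 0)
  n_genes <- length(panel_genes)
  rel <- lab == "relapse"
  a <- sum(det[rel]); b <- n_genes * sum(rel) - a
  cc <- sum(det[!rel]); d <- n_genes * sum(!rel) - cc
  structure(list(a = a, b = b, c = cc, d = d, n_genes = n_genes,
                 n_relapse = sum(rel), n_nonrelapse = sum(!rel),
                 detected_per_patient = stats::setNames(det, patients),
                 labels = stats::setNames(lab, patients)),
            class = "event_table_2x2")
}

#' 2x2 event table from raw cell counts
#'
#' @param a,b Detected / undetected events in the relapse group.
#' @param c,d Detected / undetected events in the non-relapse group.
#' @return An `event_table_2x2` list.
#' @export
event_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d), class = "event_table_2x2")
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; the Woolf interval is
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane-Anscombe correction (0.5 added to all four cells, flagged in
#' the result); per-group detection frequencies are reported from the
#' uncorrected counts.
#'
#' @param tab An `event_table_2x2` (see [build_event_table()] /
#'   [event_table()]).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, per-group
#'   `frequencies`, and `haldane` flag.
#' @export
odds_ratio_woolf <- function(tab, conf_level = 0.95) {
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  if (a + b == 0 || cc + d == 0) stop("empty group in 2x2 table")
  haldane <- any(c(a, b, cc, d) == 0)
  freq <- c(relapse = a / (a + b), no_relapse = cc / (cc + d))
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       frequencies = freq, haldane = haldane)
}

#' One-tailed Pearson chi-squared p-value for a 2x2 table
#'
#' The 1-df Pearson statistic without continuity correction,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The one-tailed p-value is half
#' the two-tailed p when the observed effect lies in the stated direction
#' (`"relapse-enriched"`: detection frequency higher in the relapse group),
#' and `1 - p/2` otherwise; a table with equal group frequencies gives 0.5.
#'
#' @param tab An `event_table_2x2`.
#' @param direction Alternative direction (only `"relapse-enriched"`).
#' @return List with `statistic`, `p_two_tailed`, `p_one_tailed`.
#' @export
one_tailed_chisq <- function(tab, direction = "relapse-enriched") {
  direction <- match.arg(direction, "relapse-enriched")
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    warning("zero margin: chi-squared p undefined")
    return(list(statistic = NA_real_, p_two_tailed = NA_real_,
                p_one_tailed = NA_real_))
  }
  stat <- n * (a * d - b * cc)^2 / prod(margins)
  p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  in_direction <- a / (a + b) > cc / (cc + d)
  p1 <- if (stat == 0) 0.5 else if (in_direction) p2 / 2 else 1 - p2 / 2
  list(statistic = stat, p_two_tailed = p2, p_one_tailed = p1)
}

#' Patient-level >= k panel-gene rule
#'
#' Fraction of patients in each outcome group whose diagnosis-plasma
#' detection count over the panel genes is at least `k`.
#'
#' @inheritParams build_event_table
#' @param k Minimum number of detected panel genes (default 2).
#' @return Named numeric vector of per-group fractions.
#' @export
patient_level_rule <- function(panel_genes, pm, labels = NULL, k = 2L,
                               allow_unknown = FALSE) {
  stopifnot(k >= 1)
  tab <- build_event_table(panel_genes, pm, labels, allow_unknown)
  det <- tab$detected_per_patient
  lab <- tab$labels
  c(relapse = mean(det[lab == "relapse"] >= k),
    no_relapse = mean(det[lab == "no_relapse"] >= k))
}

#' Full prognostic evaluation of a panel
#'
#' @inheritParams build_event_table
#' @param k Patient-level rule threshold.
#' @return List with the event table, odds-ratio result, chi-squared result,
#'   and patient-level fractions.
#' @export
evaluate_panel <- function(panel_genes, pm, labels = NULL, k = 2L,
                           allow_unknown = FALSE) {
  tab <- build_event_table(panel_genes, pm, labels, allow_unknown)
  list(table = tab,
       odds_ratio = odds_ratio_woolf(tab),
       chisq = one_tailed_chisq(tab),
       patient_rule = patient_level_rule(panel_genes, pm, labels, k,
                                         allow_unknown))
}
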