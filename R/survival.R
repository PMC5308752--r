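## Disease-free-survival estimation and comparison between mutation-defined
## patient groups. The product-limit estimator and the log-rank test are
## computed by the survival package; this module fixes the DFS conventions
## (time origin at diagnosis via the recorded follow-up months; relapse or
## death as the event, with a relapse-only mode; events before censorings
## at tied times).

#' Kaplan-Meier product-limit estimate for one group
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with
#' censored times leaving the risk set after their time and Greenwood
#' standard errors. An all-censored group yields a flat S(t) = 1 with a
#' warning.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical event indicator (TRUE = relapse/death observed).
#' @return data.frame with one row per observed event time: `time`,
#'   `n_risk`, `n_event`, `survival`, `se` (Greenwood).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time > 0))
  if (!any(event)) {
    warning("no events in group; survival is flat at 1")
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric(),
                      se = numeric()))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = FALSE)
  data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             survival = s$surv, se = s$std.err)
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [km_estimate()]: the survival probability
#' just after `t` (1 before the first event).
#'
#' @param km A [km_estimate()] result.
#' @param t Time point(s).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1.0 else km$survival[max(i)]
  }, numeric(1))
}

#' Log-rank test between two groups
#'
#' Standard (unweighted) log-rank: observed minus expected events summed
#' over event times with hypergeometric variance; p-value from the
#' chi-square distribution on 1 degree of freedom. Zero variance (e.g. no
#' events) returns p = 1 with a warning.
#'
#' @param time_a,event_a Times and event flags of the first group.
#' @param time_b,event_b Times and event flags of the second group.
#' @return List with `chisq`, `p_value`, `n` (per group), `observed` and
#'   `expected` event counts per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1, length(time_b) >= 1)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  if (!any(event)) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chisq = 0, p_value = 1, n = table(group),
                observed = c(A = 0, B = 0), expected = c(A = 0, B = 0)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  if (!is.matrix(sd$var) || sd$var[1, 1] <= 0) {
    warning("zero log-rank variance; p = 1")
    return(list(chisq = 0, p_value = 1, n = sd$n,
                observed = sd$obs, expected = sd$exp))
  }
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = sd$n, observed = sd$obs, expected = sd$exp)
}

#' Disease-free survival stratified by mutation status of one gene
#'
#' Joins the cohort matrix with the clinical table, assigns each patient to
#' the mutated or wild-type group from the gene's indicator column, and
#' compares disease-free survival (follow-up months; event = relapse or
#' death, or relapse only) between the groups. Patients absent from the
#' clinical table are dropped with a message, mirroring cohorts where the
#' complete clinical data set is available only for a subset. A gene with
#' no mutated (or no wild-type) patients yields the single-group estimate
#' and no test.
#'
#' @param M A [build_matrix()] result.
#' @param clinical Clinical table (from [read_clinical_table()]).
#' @param gene Panel gene to stratify by.
#' @param event_type `"relapse_or_death"` (default) or `"relapse_only"`.
#' @param subset Optional logical/character filter on patient ids applied
#'   before grouping (e.g. stage-I-only analyses).
#' @return List with `gene`, `groups` (per-group `km_estimate` + records),
#'   `logrank` (or `NULL`), `n_dropped`.
#' @export
dfs_by_mutation <- function(M, clinical, gene,
                            event_type = c("relapse_or_death",
                                           "relapse_only"),
                            subset = NULL) {
  event_type <- match.arg(event_type)
  if (!gene %in% M$genes) stop("gene not in panel: ", gene)
  ids <- intersect(M$patients, clinical$patient_id)
  n_dropped <- length(M$patients) - length(ids)
  if (n_dropped > 0)
    message(n_dropped, " patient(s) without clinical data dropped from the ",
            gene, " DFS analysis")
  if (!is.null(subset)) {
    ids <- if (is.character(subset)) intersect(ids, subset)
    else intersect(ids, clinical$patient_id[subset])
  }
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  event <- if (event_type == "relapse_or_death") cl$relapse | cl$death
  else cl$relapse
  mutated <- M$indicator[match(ids, M$patients), gene]
  records <- data.frame(patient_id = ids, time_months = cl$followup_months,
                        event = event,
                        group = ifelse(mutated, "mutated", "wild_type"),
                        stringsAsFactors = FALSE)
  groups <- lapply(split(records, records$group), function(r)
    list(records = r,
         km = withCallingHandlers(km_estimate(r$time_months, r$event),
                                  warning = function(w) {
                                    invokeRestart("muffleWarning")
                                  })))
  lr <- NULL
  if (all(c("mutated", "wild_type") %in% names(groups))) {
    rm_ <- groups$mutated$records
    rw <- groups$wild_type$records
    if (any(c(rm_$event, rw$event)))
      lr <- logrank_test(rm_$time_months, rm_$event,
                         rw$time_months, rw$event)
  }
  list(gene = gene, groups = groups, logrank = lr, n_dropped = n_dropped)
}

#' Write KM curves and the test summary as TSV
#'
#' @param dfs A [dfs_by_mutation()] result.
#' @param curve_path,test_path Output files.
#' @export
write_dfs_tables <- function(dfs, curve_path, test_path) {
  curves <- do.call(rbind, lapply(names(dfs$groups), function(g) {
    km <- dfs$groups[[g]]$km
    if (!nrow(km)) return(NULL)
    cbind(group = g, km)
  }))
  if (is.null(curves))
    curves <- data.frame(group = character(), time = numeric(),
                         n_risk = integer(), n_event = integer(),
                         survival = numeric(), se = numeric())
  utils::write.table(curves, curve_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  test <- data.frame(
    gene = dfs$gene,
    n_mutated = if ("mutated" %in% names(dfs$groups))
      nrow(dfs$groups$mutated$records) else 0L,
    n_wild_type = if ("wild_type" %in% names(dfs$groups))
      nrow(dfs$groups$wild_type$records) else 0L,
    chisq = if (is.null(dfs$logrank)) NA_real_ else dfs$logrank$chisq,
    p_value = if (is.null(dfs$logrank)) NA_real_ else dfs$logrank$p_value)
  utils::write.table(test, test_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(curve_path, test_path))
}
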