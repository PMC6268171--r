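# Drug-likeness filtration: strict Lipinski + Veber rules and rule-based
# ADMET proxies. Boundary semantics mirror oral-bioavailability practice:
# molecular weight must be strictly below 500 g/mol, every other bound is
# inclusive. The ADMET stage uses transparent, fixed rule-based surrogates
# for the three filter dimensions (aqueous solubility, intestinal
# absorption, blood-brain-barrier penetration); constants are documented on
# admet_proxy() and versioned with the package.

#' Lipinski + Veber drug-likeness filter
#'
#' Six rules: HBD <= 5, HBA <= 10, clogP <= 5, MW < 500 (strict),
#' rotatable bonds <= 10, TPSA <= 140 A^2. The verdict passes when the number
#' of violated rules is at most `max_violations` (0 by default: strict
#' selection with no violation tolerated).
#'
#' @param desc one row of [compute_descriptors()] output (or a list with the
#'   same fields).
#' @param max_violations maximum violations tolerated (default 0).
#' @return a `filter_report`: list with `id`, `stage`, `rules` (data.frame of
#'   rule, threshold, observed, pass), `violations`, `verdict`.
#' @export
lipinski_veber <- function(desc, max_violations = 0L) {
  rules <- data.frame(
    rule = c("hbd", "hba", "clogp", "mw", "rotb", "tpsa"),
    threshold = c(5, 10, 5, 500, 10, 140),
    observed = as.numeric(c(desc$hbd, desc$hba, desc$clogp, desc$mw,
                            desc$rotb, desc$tpsa))
  )
  rules$pass <- c(
    rules$observed[1] <= 5,
    rules$observed[2] <= 10,
    rules$observed[3] <= 5,
    rules$observed[4] < 500,      # strictly less than 500
    rules$observed[5] <= 10,
    rules$observed[6] <= 140
  )
  violations <- sum(!rules$pass)
  structure(list(id = as.character(desc$id %||% NA), stage = "lipinski_veber",
                 rules = rules, violations = violations,
                 verdict = violations <= max_violations,
                 max_violations = as.integer(max_violations)),
            class = "filter_report")
}

#' Rule-based ADMET proxy filter
#'
#' Three named proxies with fixed documented constants:
#' \describe{
#'   \item{solubility}{clogP <= 6 (very lipophilic compounds flagged
#'     insoluble).}
#'   \item{absorption}{TPSA <= 131.6 and clogP <= 5.88 (Egan-style passive
#'     intestinal absorption bounds).}
#'   \item{bbb}{TPSA <= 90 and 1 <= clogP <= 4 (CNS-penetration window);
#'     reported as a flag only, never an exclusion by default.}
#' }
#' The overall verdict is solubility AND absorption.
#'
#' @param desc one descriptor row.
#' @param bbb_required if TRUE, the BBB window also becomes exclusionary.
#' @return a `filter_report` with stage `"admet"`.
#' @export
admet_proxy <- function(desc, bbb_required = FALSE) {
  clogp <- as.numeric(desc$clogp); tpsa <- as.numeric(desc$tpsa)
  rules <- data.frame(
    rule = c("solubility", "absorption", "bbb"),
    threshold = c(6, 131.6, 90),
    observed = c(clogp, tpsa, tpsa)
  )
  rules$pass <- c(
    clogp <= 6,
    tpsa <= 131.6 && clogp <= 5.88,
    tpsa <= 90 && clogp >= 1 && clogp <= 4
  )
  verdict <- rules$pass[1] && rules$pass[2] &&
    (!bbb_required || rules$pass[3])
  structure(list(id = as.character(desc$id %||% NA), stage = "admet",
                 rules = rules, violations = sum(!rules$pass[1:2]),
                 verdict = verdict, max_violations = 0L),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report %s [%s]: %s (%d violation%s)>\n", x$id, x$stage,
              if (x$verdict) "PASS" else "FAIL", x$violations,
              if (x$violations == 1) "" else "s"))
  invisible(x)
}

#' Apply a filter to a whole descriptor table
#'
#' @param desc_df output of [compute_descriptors()].
#' @param filter `"lipinski_veber"` or `"admet"`.
#' @param ... passed to the per-molecule filter.
#' @return data.frame with columns `id`, `violations`, `verdict`.
#' @export
filter_library <- function(desc_df, filter = c("lipinski_veber", "admet"), ...) {
  filter <- match.arg(filter)
  f <- if (filter == "lipinski_veber") lipinski_veber else admet_proxy
  reps <- lapply(seq_len(nrow(desc_df)), function(i) f(desc_df[i, ], ...))
  data.frame(id = vapply(reps, function(r) r$id, character(1)),
             violations = vapply(reps, function(r) r$violations, numeric(1)),
             verdict = vapply(reps, function(r) r$verdict, logical(1)))
}

#' Serialize filter reports to rule-level CSV rows
#'
#' @param reports list of `filter_report`.
#' @return data.frame, one row per rule per molecule.
#' @export
filter_report_rows <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    cbind(data.frame(id = r$id, stage = r$stage), r$rules,
          data.frame(verdict = r$verdict))))
}
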