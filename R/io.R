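# Long-format observation tables (NONMEM-style dialect) and structured
# configuration files.
#
# Table columns: ID (subject), TIME (days), DVID (1 RET, 2 RBC, 3 MCH,
# 4 IRF, 5 Hb_tot), DV (value in the endpoint's unit; IRF as a fraction),
# DOSE (mg), AUC (mg/L*h), SEX (M/F), ARM (label).  Comma-delimited CSV,
# '.' decimal, missing DV as an empty field.

#' Read an observation table
#'
#' Validates the dialect on read: `(ID, TIME, DVID)` unique, `TIME >= 0`,
#' `DVID` in 1..5.  Parse errors name the offending row.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_obs_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DVID", "DV", "DOSE", "AUC", "SEX", "ARM")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("observation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!d$DVID %in% 1:5)
  if (length(bad))
    stop("unknown DVID ", d$DVID[bad[1]], " at row ", bad[1], call. = FALSE)
  bad <- which(d$TIME < 0)
  if (length(bad))
    stop("negative TIME at row ", bad[1], call. = FALSE)
  key <- paste(d$ID, d$TIME, d$DVID)
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate (ID, TIME, DVID) key at row ", bad[1], call. = FALSE)
  d
}

#' Write an observation table
#'
#' Canonical form: columns in dialect order, sorted by (ID, TIME, DVID),
#' no row names, empty field for missing DV.  `write` then `read` is the
#' identity on this form.
#'
#' @param table data.frame in the observation dialect.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_obs_table <- function(table, path) {
  cols <- c("ID", "TIME", "DVID", "DV", "DOSE", "AUC", "SEX", "ARM")
  table <- table[do.call(order, table[c("ID", "TIME", "DVID")]), cols]
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Default configuration as a nested list
#'
#' Mirrors the model's parameter symbols: structural typical values, IIV
#' percent CVs, residual error per endpoint, and the trial design.
#'
#' @return Nested list suitable for [write_config()].
#' @export
default_config <- function() {
  pop <- population_model()
  list(
    parameters = pop$typical[c("LS_PRE", "LS_RBC", "RET_0", "RBC_0",
                               "MCH_0", "IRF_0", "gamma_FB", "k_TOL",
                               "Imax", "AUC50", "n_CTR",
                               "rbc_diff_female", "feedback_sign")],
    iiv_cv = as.list(pop$iiv_cv),
    residual = lapply(pop$residual, function(s)
      list(kind = s$kind, sd_add = s$sd_add, sd_prop = s$sd_prop)),
    design = {
      dsn <- trial_design()
      list(dose = dsn$arms$dose, n = dsn$arms$n, visits = dsn$visits,
           t_on = dsn$t_on, t_off = dsn$t_off,
           c_exp = dsn$c_exp, auc_cv = dsn$auc_cv)
    })
}

#' Read / write a model configuration (YAML)
#'
#' Unknown top-level or parameter keys are rejected with the list of valid
#' keys, so typos fail loudly.
#'
#' @param path YAML file path.
#' @return For `read_config`: list with `pop` (an `ery_population`) and
#'   `design` (an `ery_design`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  chk <- function(got, valid, where) {
    bad <- setdiff(names(got), valid)
    if (length(bad))
      stop("invalid config key(s) in ", where, ": ",
           paste(bad, collapse = ", "), "; valid keys: ",
           paste(valid, collapse = ", "), call. = FALSE)
  }
  chk(cfg, names(base), "top level")
  if (!is.null(cfg$parameters)) chk(cfg$parameters,
                                    names(base$parameters), "parameters")
  if (!is.null(cfg$iiv_cv)) chk(cfg$iiv_cv, names(formals(model_parameters)),
                                "iiv_cv")
  merged <- utils::modifyList(base, cfg)
  typ <- do.call(model_parameters, merged$parameters)
  res <- lapply(merged$residual, function(s)
    residual_spec(s$kind, sd_add = s$sd_add, sd_prop = s$sd_prop))
  pop <- population_model(typical = typ,
                          iiv_cv = unlist(merged$iiv_cv),
                          residual = res)
  dsn <- trial_design(arms = data.frame(dose = merged$design$dose,
                                        n = merged$design$n),
                      visits = merged$design$visits,
                      t_on = merged$design$t_on, t_off = merged$design$t_off,
                      c_exp = merged$design$c_exp,
                      auc_cv = merged$design$auc_cv)
  list(pop = pop, design = dsn)
}

#' @rdname read_config
#' @param config nested list, e.g. from [default_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
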