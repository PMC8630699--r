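#' Model parameter set
#'
#' Every model quantity with its baseline value, one-way range and
#' probabilistic-sensitivity-analysis distribution family. Ranges are 95%
#' confidence intervals where reported (hazard ratios) and otherwise ±20% of
#' the baseline. Distribution families: `lognormal` for hazard ratios,
#' `beta` for utilities and probabilities, `gamma` for costs, `fixed` for
#' the survival-curve parameters (which carry no uncertainty distribution).
#'
#' @return A `data.frame` of class `parameter_set` with columns `name`,
#'   `label`, `baseline`, `min`, `max`, `distribution`.
#' @export
default_parameters <- function() {
  p <- list(
    # name, label, baseline, min, max, distribution
    c("os_theta", "Log-logistic OS theta, ipilimumab", 0.03916796, NA, NA, "fixed"),
    c("os_kappa", "Log-logistic OS kappa, ipilimumab", 1.52458, NA, NA, "fixed"),
    c("pfs_theta", "Log-logistic PFS theta, ipilimumab", 0.1380415, NA, NA, "fixed"),
    c("pfs_kappa", "Log-logistic PFS kappa, ipilimumab", 1.922389, NA, NA, "fixed"),
    c("hr_os", "HR of combination vs ipilimumab, OS", 0.50, 0.38, 0.66, "lognormal"),
    c("hr_pfs", "HR of combination vs ipilimumab, PFS", 0.69, 0.55, 0.87, "lognormal"),
    c("resp_combo", "Response percentage, combination arm", 0.31, 0.25, 0.37, "beta"),
    c("resp_ipi", "Response percentage, ipilimumab arm", 0.13, 0.10, 0.16, "beta"),
    c("u_response", "Utility, complete/partial response", 0.88, 0.70, 1.00, "beta"),
    c("u_stable", "Utility, stable disease", 0.80, 0.64, 0.96, "beta"),
    c("u_progressed", "Utility, progressed disease", 0.52, 0.42, 0.62, "beta"),
    c("price_ipilimumab_mg", "Ipilimumab per mg", 166, 133, 199, "gamma"),
    c("price_nivolumab_mg", "Nivolumab per mg", 30, 24, 36, "gamma"),
    c("price_pembrolizumab_mg", "Pembrolizumab per mg", 55, 44, 66, "gamma"),
    c("cost_bsc", "Best supportive care", 4492, 3594, 5390, "gamma"),
    c("cost_mgmt_on_tx_week", "Disease management in PFD on treatment, per week", 189, 151, 227, "gamma"),
    c("cost_mgmt_off_tx_week", "Disease management in PFD off treatment, per week", 590, 472, 708, "gamma"),
    c("cost_terminal", "Terminal care", 18042, 14434, 21650, "gamma"),
    c("cost_admin_first_hr", "Administration, first hour", 148, 119, 178, "gamma"),
    c("cost_admin_addl_hr", "Administration, additional hour", 31, 25, 38, "gamma"))
  df <- do.call(rbind, lapply(p, function(x)
    data.frame(name = x[1], label = x[2], baseline = as.numeric(x[3]),
               min = as.numeric(x[4]), max = as.numeric(x[5]),
               distribution = x[6])))
  validate_parameter_set(df)
}

validate_parameter_set <- function(df) {
  need <- c("name", "label", "baseline", "min", "max", "distribution")
  if (!all(need %in% names(df))) stop("parameter set needs columns: ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicated parameter names")
  varied <- df$distribution != "fixed"
  bad <- varied & !(df$min <= df$baseline & df$baseline <= df$max)
  if (any(bad, na.rm = TRUE))
    stop("min <= baseline <= max violated for: ",
         paste(df$name[which(bad)], collapse = ", "))
  if (!all(df$distribution %in% c("gamma", "lognormal", "beta", "fixed")))
    stop("unknown distribution family")
  structure(df, class = c("parameter_set", "data.frame"))
}

#' Named list of baseline parameter values
#'
#' @param params A [default_parameters()]-style `parameter_set`.
#' @return Named list `name -> baseline`.
#' @export
baseline_values <- function(params = default_parameters()) {
  stats::setNames(as.list(params$baseline), params$name)
}

#' Read / write a parameter set as CSV
#'
#' The bundled file `inst/extdata/parameters.csv` round-trips through these
#' functions.
#'
#' @param path CSV file path.
#' @return For `read_parameter_set`, a `parameter_set`; for
#'   `write_parameter_set`, `path` invisibly.
#' @export
read_parameter_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_parameter_set(df)
}

#' @rdname read_parameter_set
#' @param params The `parameter_set` to write.
#' @export
write_parameter_set <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' Subgroup hazard-ratio table
#'
#' PFS and OS hazard ratios (with 95% CIs) of combination versus ipilimumab
#' in each pre-specified clinical subgroup of the source comparison.
#'
#' @return `data.frame` with columns `subgroup`, `pfs_hr`, `pfs_lo`,
#'   `pfs_hi`, `os_hr`, `os_lo`, `os_hi`.
#' @export
subgroup_table <- function() {
  tx <- "subgroup|pfs_hr|pfs_lo|pfs_hi|os_hr|os_lo|os_hi
Male|0.69|0.51|0.92|0.45|0.31|0.64
Female|0.70|0.48|1.01|0.60|0.39|0.92
Age < 64 yr|0.72|0.52|1.00|0.54|0.37|0.80
Age >= 64 yr|0.71|0.51|0.98|0.48|0.32|0.73
BRAF mutant|1.01|0.66|1.56|0.73|0.43|1.26
NRAS mutant|0.62|0.36|1.07|0.48|0.25|0.91
BRAF & NRAS WT|0.58|0.42|0.81|0.46|0.31|0.69
ECOG PS 0|0.68|0.49|0.95|0.47|0.31|0.72
ECOG PS >= 1|0.99|0.70|1.42|0.82|0.56|1.21
Stage III/M1A/M1B|0.74|0.48|1.15|0.53|0.30|0.93
Stage M1C/M1D|0.68|0.51|0.89|0.50|0.37|0.69
Brain metastases: no|0.79|0.52|1.18|0.51|0.31|0.82
Brain metastases: yes|0.64|0.48|0.84|0.47|0.33|0.66
Lung metastases: no|0.73|0.54|0.98|0.54|0.38|0.78
Lung metastases: yes|0.69|0.48|1.00|0.48|0.31|0.74
Liver metastases: no|0.68|0.45|1.04|0.59|0.37|0.93
Liver metastases: yes|0.71|0.54|0.94|0.48|0.34|0.67
LDH = UNL|0.75|0.54|1.02|0.45|0.30|0.69
LDH > UNL|0.56|0.38|0.83|0.47|0.30|0.72
PD-(L)1 setting: adjuvant|0.52|0.22|1.25|0.81|0.17|3.90
PD-(L)1 setting: metastatic|0.74|0.58|0.94|0.54|0.40|0.71
Resistance: innate|0.75|0.56|0.99|0.52|0.37|0.71
Resistance: acquired|0.71|0.44|1.14|0.56|0.31|1.01
Best response to PD-(L)1: SD/PD|0.72|0.55|0.95|0.50|0.36|0.68
Best response to PD-(L)1: CR/PR|0.79|0.45|1.40|0.70|0.34|1.43
Best response to PD-(L)1: not applicable|0.52|0.22|1.25|0.81|0.17|3.90
Time to progression <= 3 mo|0.63|0.46|0.87|0.45|0.31|0.64
Time to progression > 3 mo|0.75|0.53|1.05|0.52|0.34|0.81
Time from PD-(L)1 <= 1 mo|0.72|0.52|0.99|0.54|0.37|0.80
Time from PD-(L)1 > 1 mo|0.69|0.49|0.96|0.47|0.31|0.70
Interim systemic treatment: no|0.67|0.52|0.87|0.51|0.38|0.69
Interim systemic treatment: yes|0.68|0.36|1.30|0.34|0.16|0.75"
  utils::read.csv(text = tx, sep = "|", stringsAsFactors = FALSE)
}

#' Write the bundled parameter and subgroup fixtures
#'
#' Emits `parameters.csv` and `subgroups.csv` under `dir`, in the format
#' read back by [read_parameter_set()] and [utils::read.csv()].
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_parameter_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "parameters.csv")
  p2 <- file.path(dir, "subgroups.csv")
  write_parameter_set(default_parameters(), p1)
  utils::write.csv(subgroup_table(), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

# build model objects from a named list of parameter values
values_to_inputs <- function(v, cfg) {
  os0 <- surv_spec("loglogistic", c(theta = v$os_theta, kappa = v$os_kappa))
  pfs0 <- surv_spec("loglogistic", c(theta = v$pfs_theta, kappa = v$pfs_kappa))
  prices <- price_table(
    ipilimumab_per_mg = v$price_ipilimumab_mg,
    nivolumab_per_mg = v$price_nivolumab_mg,
    pembrolizumab_per_mg = v$price_pembrolizumab_mg,
    bsc = v$cost_bsc,
    mgmt_pfd_on_tx_per_week = v$cost_mgmt_on_tx_week,
    mgmt_pfd_off_tx_per_week = v$cost_mgmt_off_tx_week,
    terminal_care = v$cost_terminal,
    admin_first_hour = v$cost_admin_first_hr,
    admin_additional_hour = v$cost_admin_addl_hr)
  list(os0 = os0, pfs0 = pfs0, prices = prices)
}
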