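# The model's parameter table: 22 labeled inputs (letters A-H, J-W; "I" is
# intentionally skipped so labels line up with the published input table),
# each with a distribution family and hyperparameters. Proportions are stored
# as fractions in [0, 1], never percentages.

param_labels <- function() {
  c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L",
    "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W")
}

dist_families <- function() c("normal", "betapert", "lognormal", "point")

param_units <- function() {
  c("visits/year", "proportion", "USD", "minutes", "USD/bed-hour",
    "USD/admission")
}

new_parameter_table <- function(df, metadata = "") {
  rownames(df) <- NULL
  structure(df, metadata = metadata,
            class = c("ban_parameter_table", "data.frame"))
}

#' The packaged default parameter table
#'
#' All 22 model inputs: national ED visit volumes, diagnosis shares,
#' nebulizer-treatment shares, baseline admission rates, device unit prices,
#' length-of-stay effects, percent reductions in admission after converting
#' to BAN, and unit costs. Visit volumes, shares, rates, reductions, and unit
#' costs carry normal uncertainty with the published SDs used verbatim;
#' device prices carry BetaPERT (min, most-likely, max) distributions;
#' length-of-stay effects carry lognormal distributions matched to the stated
#' arithmetic mean and SD, reflecting the right skew of ED stay durations.
#'
#' @return A `ban_parameter_table`: a data frame with one row per label and
#'   columns `label`, `name`, `dist_family`, `mean`, `sd`, `min`, `mode`,
#'   `max`, `units`, `source`.
#' @examples
#' tab <- default_parameter_table()
#' subset(tab, label %in% c("A", "M", "O"))
#' @export
default_parameter_table <- function() {
  row <- function(label, name, family, units, source,
                  mean = NA_real_, sd = NA_real_,
                  min = NA_real_, mode = NA_real_, max = NA_real_) {
    data.frame(label = label, name = name, dist_family = family,
               mean = mean, sd = sd, min = min, mode = mode, max = max,
               units = units, source = source, stringsAsFactors = FALSE)
  }
  nh <- "NHAMCS 2016-2021"
  df <- rbind(
    row("A", "Annual US ED visit volume (adults)", "normal",
        "visits/year", nh, mean = 111e6, sd = 11e6),
    row("B", "Annual US ED visits (pediatrics excluding <2 years old)",
        "normal", "visits/year", nh, mean = 22e6, sd = 2.2e6),
    row("C", "Share of ED visits for asthma exacerbation (pediatrics)",
        "normal", "proportion", nh, mean = 0.022, sd = 0.0022),
    row("D", "Share of ED visits for asthma exacerbation (adults)",
        "normal", "proportion", nh, mean = 0.0086, sd = 0.0010),
    row("E", "Share of ED visits for COPD/emphysema exacerbation",
        "normal", "proportion", nh, mean = 0.0094, sd = 0.0010),
    row("F", "Share of pediatric asthma visits receiving nebulizer therapy",
        "normal", "proportion", nh, mean = 0.66, sd = 0.066),
    row("G", "Share of adult asthma visits receiving nebulizer therapy",
        "normal", "proportion", nh, mean = 0.57, sd = 0.050),
    row("H", "Share of COPD/emphysema visits receiving nebulizer therapy",
        "normal", "proportion", nh, mean = 0.41, sd = 0.041),
    row("J", "Admission rate after nebulizer therapy (pediatric asthma)",
        "normal", "proportion", nh, mean = 0.077, sd = 0.007),
    row("K", "Admission rate after nebulizer therapy (adult asthma)",
        "normal", "proportion", nh, mean = 0.0576, sd = 0.0058),
    row("L", "Admission rate after nebulizer therapy (COPD/emphysema)",
        "normal", "proportion", nh, mean = 0.412, sd = 0.0412),
    row("M", "Per-unit price of BAN (AeroEclipse II)", "betapert",
        "USD", "IQVIA medical device and supply purchase data",
        min = 5.43, mode = 5.45, max = 9.07),
    row("N", "Per-unit price of continuous nebulizer", "betapert",
        "USD", "IQVIA medical device and supply purchase data",
        min = 0.69, mode = 0.75, max = 1.83),
    row("O", "ED LOS reduction from BAN, pediatric asthma (minutes)",
        "lognormal", "minutes",
        "Single-site prospective nonrandomized study (159 patients)",
        mean = 59, sd = 29.5),
    row("P", "ED LOS increase from BAN, adult asthma (minutes)",
        "lognormal", "minutes",
        "Single-site prospective randomized study (54 patients)",
        mean = 13.1, sd = 1.31),
    row("Q", "Admission reduction after converting to BAN (pediatric asthma)",
        "normal", "proportion",
        "Single-site randomized study (149 patients)",
        mean = 0.333, sd = 0.0333),
    row("R", "Admission reduction after converting to BAN (adult asthma)",
        "normal", "proportion", "Single-site randomized study (2-year)",
        mean = 0.72, sd = 0.072),
    row("S", "Admission reduction after converting to BAN (COPD)",
        "normal", "proportion",
        "Single-site randomized study (3600 patients, 2-year)",
        mean = 0.456, sd = 0.046),
    row("T", "ED patient bed-hour cost (average)", "normal",
        "USD/bed-hour", "Single-site urban academic cost analysis",
        mean = 58.20, sd = 5.80),
    row("U", "Cost per admission, pediatric asthma exacerbation", "normal",
        "USD/admission", "CMS", mean = 5200, sd = 520),
    row("V", "Cost per admission, adult asthma exacerbation", "normal",
        "USD/admission", "HCUP Nationwide Inpatient Dataset",
        mean = 6688, sd = 668.8),
    row("W", "Cost per admission, COPD/emphysema exacerbation", "normal",
        "USD/admission", "Systematic literature review",
        mean = 6852, sd = 685.2)
  )
  new_parameter_table(df, metadata = "bansim packaged default parameter table")
}

#' Validate a parameter table
#'
#' Checks the table's structural and per-parameter invariants and returns
#' every violation as data (not an error): exactly the 22 expected labels,
#' recognised distribution families, family-specific hyperparameter
#' requirements (normal/lognormal: `mean > 0`, `sd >= 0`, no range fields;
#' BetaPERT: `min <= mode <= max`, `min < max`, no moment fields; point:
#' finite `mean >= 0`), and proportions with central value in `[0, 1]`.
#' An empty report means the table is usable by the sampler.
#'
#' @param table A `ban_parameter_table` (or any data frame with its columns).
#' @return A data frame with columns `label` and `message`, one row per
#'   violation; zero rows when the table is valid.
#' @examples
#' nrow(validate_parameter_table(default_parameter_table())) # 0
#' @export
validate_parameter_table <- function(table) {
  findings <- list()
  add <- function(label, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(label = label, message = message, stringsAsFactors = FALSE)
  }

  expected <- param_labels()
  missing <- setdiff(expected, table$label)
  extra <- setdiff(table$label, expected)
  dup <- unique(table$label[duplicated(table$label)])
  for (l in missing) add(l, "required label is missing")
  for (l in extra) add(l, "unexpected label (only A-H, J-W are allowed)")
  for (l in dup) add(l, "label appears more than once")

  num_or_na <- function(x) is.na(x) | is.finite(x)
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    l <- r$label
    if (!r$dist_family %in% dist_families()) {
      add(l, paste0("unknown dist_family '", r$dist_family, "'"))
      next
    }
    if (!r$units %in% param_units()) {
      add(l, paste0("unknown units '", r$units, "'"))
    }
    if (!all(num_or_na(c(r$mean, r$sd, r$min, r$mode, r$max)))) {
      add(l, "non-finite hyperparameter value")
      next
    }
    if (r$dist_family %in% c("normal", "lognormal")) {
      if (is.na(r$mean) || r$mean <= 0) add(l, "mean must be set and > 0")
      if (is.na(r$sd) || r$sd < 0) add(l, "sd must be set and >= 0")
      if (!all(is.na(c(r$min, r$mode, r$max)))) {
        add(l, "min/mode/max must be unset for normal/lognormal")
      }
    } else if (r$dist_family == "betapert") {
      if (anyNA(c(r$min, r$mode, r$max))) {
        add(l, "min, mode, and max must all be set for betapert")
      } else {
        if (!(r$min <= r$mode && r$mode <= r$max)) {
          add(l, "betapert requires min <= mode <= max")
        }
        if (!(r$min < r$max)) add(l, "betapert requires min < max")
      }
      if (!all(is.na(c(r$mean, r$sd)))) {
        add(l, "mean/sd must be unset for betapert (the mean is derived)")
      }
    } else if (r$dist_family == "point") {
      if (is.na(r$mean) || r$mean < 0) add(l, "point mean must be set and >= 0")
      if (!all(is.na(c(r$min, r$mode, r$max)))) {
        add(l, "min/mode/max must be unset for point")
      }
    }
    if (identical(r$units, "proportion")) {
      central <- if (r$dist_family == "betapert") r$mode else r$mean
      if (!is.na(central) && (central < 0 || central > 1)) {
        add(l, paste0("proportion central value ", central,
                      " outside [0, 1]"))
      }
    }
  }
  if (length(findings) == 0L) {
    data.frame(label = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

assert_valid_parameter_table <- function(table) {
  rep <- validate_parameter_table(table)
  if (nrow(rep) > 0L) {
    stop("invalid parameter table:\n",
         paste0("  [", rep$label, "] ", rep$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(table)
}

table_to_config <- function(table) {
  params <- list()
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    entry <- list(name = r$name, dist_family = r$dist_family,
                  units = r$units, source = r$source)
    for (f in c("mean", "sd", "min", "mode", "max")) {
      if (!is.na(r[[f]])) entry[[f]] <- r[[f]]
    }
    params[[r$label]] <- entry
  }
  list(metadata = attr(table, "metadata"), parameters = params)
}

config_to_table <- function(config, where = "config") {
  if (is.null(config$parameters)) {
    stop("parameter config has no `parameters` block (", where, ")")
  }
  inherit <- isTRUE(config$inherit_defaults)
  base <- if (inherit) default_parameter_table() else NULL
  labels <- names(config$parameters)

  if (!inherit) {
    missing <- setdiff(param_labels(), labels)
    if (length(missing) > 0L) {
      stop("parameter config is missing label(s): ",
           paste(missing, collapse = ", "), " (", where, ")")
    }
  }

  rows <- list()
  for (l in labels) {
    entry <- config$parameters[[l]]
    r <- data.frame(label = l,
                    name = if (is.null(entry$name)) "" else entry$name,
                    dist_family = if (is.null(entry$dist_family))
                      NA_character_ else entry$dist_family,
                    mean = NA_real_, sd = NA_real_, min = NA_real_,
                    mode = NA_real_, max = NA_real_,
                    units = if (is.null(entry$units))
                      NA_character_ else entry$units,
                    source = if (is.null(entry$source)) "" else entry$source,
                    stringsAsFactors = FALSE)
    for (f in c("mean", "sd", "min", "mode", "max")) {
      v <- entry[[f]]
      if (!is.null(v)) {
        if (!is.numeric(v) || length(v) != 1L) {
          stop("malformed number for field `", f, "` of label `", l,
               "` (", where, ")")
        }
        r[[f]] <- as.numeric(v)
      }
    }
    rows[[l]] <- r
  }
  df <- do.call(rbind, rows)

  if (inherit) {
    keep <- base[!base$label %in% df$label, , drop = FALSE]
    df <- rbind(as.data.frame(keep), df)
  }
  df <- df[order(match(df$label, param_labels())), , drop = FALSE]
  meta <- if (is.null(config$metadata)) "" else config$metadata
  new_parameter_table(df, metadata = meta)
}

#' Read a parameter table from a YAML config file
#'
#' Performs schema-level parsing only (labels present, numeric fields
#' numeric); invariant checking is left to [validate_parameter_table()] so
#' that a linting workflow can report all findings. Use
#' [load_parameter_table()] to read and validate in one step.
#'
#' The config is a YAML document with an optional `metadata` string, an
#' optional `inherit_defaults: true` flag (missing labels are then filled
#' from the packaged table), and a `parameters` mapping from label to the
#' fields `name`, `dist_family`, `mean`, `sd`, `min`, `mode`, `max`,
#' `units`, `source`.
#'
#' @param path Path to a YAML file.
#' @return A `ban_parameter_table` (not yet invariant-checked).
#' @export
read_parameter_table <- function(path) {
  config <- yaml::read_yaml(path)
  config_to_table(config, where = path)
}

#' Load and validate a parameter table
#'
#' Reads a YAML parameter config (see [read_parameter_table()] for the
#' schema) and errors with the full list of invariant violations if the
#' table is not usable.
#'
#' @inheritParams read_parameter_table
#' @return A validated `ban_parameter_table`.
#' @export
load_parameter_table <- function(path) {
  assert_valid_parameter_table(read_parameter_table(path))
}

#' Write a parameter table to disk
#'
#' `yaml` is the round-trippable config format read back by
#' [load_parameter_table()]; `csv` is a flat one-row-per-label export for
#' spreadsheets (not re-importable).
#'
#' @param table A `ban_parameter_table`.
#' @param path Output file path.
#' @param format `"yaml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path, format = c("yaml", "csv")) {
  format <- match.arg(format)
  if (format == "yaml") {
    yaml::write_yaml(table_to_config(table), path, precision = 15L)
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}

#' @export
print.ban_parameter_table <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat("<ban_parameter_table> ", nrow(x), " parameters",
      if (!is.null(meta) && nzchar(meta)) paste0(" -- ", meta),
      "\n", sep = "")
  print(as.data.frame(x)[, c("label", "dist_family", "mean", "sd",
                             "min", "mode", "max", "units")], ...)
  invisible(x)
}
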