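# Case-mix file formats and report rendering.
#
# A case-mix file carries three blocks: the economic context, the options
# table (one row per patient group) and the chosen designation. CSV encodes
# the context and chosen blocks as leading `# key: value` comment lines
# above the header row; JSON and YAML nest them naturally.

.oc_meta_keys <- c("threshold", "occupancy_rate", "excess_demand", "objective",
                   "perspective", "currency", "chosen")

#' Read a case mix from CSV, JSON or YAML
#'
#' @param path File path; the format is inferred from the extension unless
#'   given explicitly.
#' @param format `"csv"`, `"json"` or `"yaml"`.
#' @return A list with `case_mix` and `context`, as [worked_example()].
#' @examples
#' path <- system.file("extdata", "worked-example.csv", package = "oppcost")
#' read_case_mix(path)
#' @export
read_case_mix <- function(path, format = NULL) {
  if (!file.exists(path)) {
    oc_abort(sprintf("File not found: %s", path), class = "oppcost_parse_error")
  }
  format <- format %||% infer_format(path)
  parsed <- switch(
    format,
    csv = read_case_mix_csv(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = yaml::read_yaml(path),
    oc_abort(sprintf("Unsupported format '%s'.", format), class = "oppcost_parse_error")
  )
  build_case_mix_file(parsed, path)
}

infer_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = "csv", json = "json", yaml = , yml = "yaml",
         oc_abort(sprintf("Cannot infer a case-mix format from '%s'.", path),
                  class = "oppcost_parse_error"))
}

read_case_mix_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  options <- readr::read_csv(I(paste(body, collapse = "\n")),
                             show_col_types = FALSE, progress = FALSE)
  context <- meta[setdiff(names(meta), c("chosen", grep("^chosen_", names(meta), value = TRUE)))]
  chosen <- meta[["chosen"]]
  chosen_fields <- meta[grep("^chosen_", names(meta))]
  if (length(chosen_fields)) {
    names(chosen_fields) <- sub("^chosen_", "", names(chosen_fields))
    chosen <- chosen_fields
  }
  list(context = context, options = options, chosen = chosen)
}

as_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
as_flag <- function(x, default) {
  if (is.null(x)) default else tolower(as.character(x)) %in% c("true", "1", "yes")
}

build_case_mix_file <- function(parsed, path) {
  ctx <- parsed$context
  if (is.null(ctx$threshold)) {
    oc_abort(sprintf("Case-mix file %s lacks a `threshold` in its context block.", path),
             class = "oppcost_parse_error")
  }
  context <- economic_context(
    threshold = as_num(ctx$threshold),
    occupancy_rate = as_num(ctx$occupancy_rate) %||% 1,
    excess_demand = as_flag(ctx$excess_demand, TRUE),
    objective = as.character(ctx$objective %||% "nmb"),
    perspective = as.character(ctx$perspective %||% "provider"),
    currency = as.character(ctx$currency %||% "£")
  )
  options <- parsed$options
  if (!is.data.frame(options)) {
    # YAML carries the table as a list of row records
    options <- dplyr::bind_rows(lapply(options, tibble::as_tibble_row))
  }
  options <- as_tibble(options)
  chosen <- parsed$chosen
  if (is.null(chosen)) {
    oc_abort(sprintf("Case-mix file %s lacks a `chosen` block.", path),
             class = "oppcost_parse_error")
  }
  if (is.list(chosen) && !is.null(chosen$los_total)) {
    chosen <- chosen_option(
      id = as.character(chosen$id %||% "chosen"),
      los_total = as_num(chosen$los_total),
      expenditure_total = as_num(chosen$expenditure_total),
      variable_cost_total = as_num(chosen$variable_cost_total),
      revenue_total = as_num(chosen$revenue_total),
      qaly_gain_total = as_num(chosen$qaly_gain_total)
    )
  } else if (is.list(chosen)) {
    chosen <- as.character(chosen$id)
  } else {
    chosen <- as.character(chosen)
  }
  list(case_mix = case_mix(options, chosen), context = context)
}

#' Write a case mix to CSV, JSON or YAML
#'
#' The written file round-trips: reading it back reproduces the same case
#' mix and context.
#'
#' @param cm A [case_mix()].
#' @param context An [economic_context()].
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"yaml"`; inferred from the extension
#'   by default.
#' @return `path`, invisibly.
#' @export
write_case_mix <- function(cm, context, path, format = NULL) {
  stopifnot(inherits(cm, "oc_case_mix"), inherits(context, "oc_context"))
  format <- format %||% infer_format(path)
  ctx <- list(threshold = context$threshold,
              occupancy_rate = context$occupancy_rate,
              excess_demand = context$excess_demand,
              objective = context$objective,
              perspective = context$perspective,
              currency = context$currency)
  chosen <- if (inherits(cm$chosen, "oc_chosen")) {
    ch <- cm$chosen
    Filter(Negate(is.null),
           list(id = ch$id, los_total = ch$los_total,
                expenditure_total = ch$expenditure_total,
                variable_cost_total = ch$variable_cost_total,
                revenue_total = ch$revenue_total,
                qaly_gain_total = ch$qaly_gain_total))
  } else {
    cm$chosen_id
  }
  if (format == "csv") {
    num <- function(x) {
      if (is.numeric(x)) format(x, digits = 17, scientific = FALSE, trim = TRUE) else as.character(x)
    }
    meta <- c(
      vapply(names(ctx), function(k) sprintf("# %s: %s", k, num(ctx[[k]])), character(1)),
      if (is.character(chosen)) {
        sprintf("# chosen: %s", chosen)
      } else {
        vapply(names(chosen), function(k) sprintf("# chosen_%s: %s", k, num(chosen[[k]])),
               character(1))
      }
    )
    body <- readr::format_csv(cm$options, na = "")
    writeLines(c(meta, sub("\n$", "", body)), path, useBytes = TRUE)
  } else if (format == "json") {
    jsonlite::write_json(list(context = ctx, chosen = chosen, options = cm$options),
                         path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else if (format == "yaml") {
    yaml::write_yaml(list(context = ctx, chosen = chosen,
                          options = df_to_rowlist(cm$options)),
                     path, precision = 15)
  } else {
    oc_abort(sprintf("Unsupported format '%s'.", format), class = "oppcost_parse_error")
  }
  invisible(path)
}

df_to_rowlist <- function(df) {
  purrr::pmap(df, function(...) Filter(function(v) !is.na(v), list(...)))
}

#' Format money for reports
#'
#' Rounds to two decimals (dropped when integral), adds thousands separators
#' and the currency label; negative amounts are prefixed with a minus sign.
#'
#' @param x Numeric.
#' @param currency Currency label.
#' @return Character.
#' @examples
#' format_money(14000) # "£14,000"
#' @export
format_money <- function(x, currency = "£") {
  sign <- ifelse(x < 0, "-", "")
  mag <- format(round(abs(x), 2), big.mark = ",", trim = TRUE,
                scientific = FALSE, drop0trailing = TRUE)
  paste0(sign, currency, mag)
}

format_quantity <- function(value, unit, currency) {
  if (unit == "money") format_money(value, currency)
  else format(round(value, 4), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

.oc_methodology_titles <- c(
  A = "Methodology A: Units of the second-best alternative forgone",
  B = "Methodology B: Net benefit of the second-best alternative forgone",
  C = "Methodology C: Expenditure of the alternative chosen",
  D = "Methodology D: Expenditure of the alternative chosen + highest net benefit forgone"
)

#' Render valuation results (and optionally an optimality assessment)
#'
#' Produces a deterministic textual report: the approach-by-approach
#' valuation grouped under its methodology headings and, when an assessment
#' is supplied, the per-option totals with the recommended methodology and
#' the true opportunity cost. Output is byte-identical for identical inputs.
#'
#' @param results An `oc_results` tibble from [evaluate_all()].
#' @param assessment Optional `oc_optimality` from [assess_optimality()].
#' @param format `"table"`, `"csv"`, `"json"` or `"markdown"`.
#' @return A single character string. When no approach could be computed the
#'   string is an explanatory stub and carries attribute `empty = TRUE` (the
#'   command-line interface maps this onto a non-success exit status).
#' @export
write_report <- function(results, assessment = NULL,
                         format = c("table", "markdown", "csv", "json")) {
  format <- rlang::arg_match(format)
  if (is.null(results) || nrow(results) == 0) {
    return(structure(
      "No opportunity-cost approach could be computed: the case mix lacks the required inputs for every approach.\n",
      empty = TRUE))
  }
  currency <- attr(results, "context")$currency %||% "£"
  switch(format,
    markdown = report_markdown(results, assessment, currency),
    table = report_table(results, assessment, currency),
    csv = report_csv(results, assessment),
    json = report_json(results, assessment)
  )
}

rendered_values <- function(results, currency) {
  vapply(seq_len(nrow(results)), function(k) {
    v <- format_quantity(results$value[k], results$unit[k], currency)
    if (results$approach_id[k] == "8" && !is.na(results$secondary_value[k])) {
      v <- sprintf("%s & %s", v,
                   format(results$secondary_value[k], big.mark = ",", trim = TRUE,
                          drop0trailing = TRUE))
    }
    v
  }, character(1))
}

report_markdown <- function(results, assessment, currency) {
  vals <- rendered_values(results, currency)
  lines <- c(
    sprintf("## Opportunity-cost valuation (chosen: %s)", attr(results, "chosen_id")),
    "",
    "| Approach | Description | Result |",
    "|---|---|---|"
  )
  for (m in intersect(c("A", "B", "C", "D"), results$methodology)) {
    lines <- c(lines, sprintf("| **%s** | | |", .oc_methodology_titles[[m]]))
    idx <- which(results$methodology == m)
    lines <- c(lines, sprintf("| %s | %s | %s |",
                              results$approach_id[idx],
                              results$description[idx], vals[idx]))
  }
  if (!is.null(assessment)) {
    lines <- c(lines, "", assessment_markdown(assessment, currency))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

assessment_markdown <- function(a, currency) {
  s <- a$assessments
  fm <- function(x) format_money(x, currency)
  n_lab <- sprintf("%s (n = %s%s)", s$id,
                   format(round(s$n_forgone, 2), trim = TRUE, drop0trailing = TRUE),
                   ifelse(s$chosen, "", " forgone"))
  lines <- c(
    "## Optimality assessment",
    "",
    paste0("| | ", paste(n_lab, collapse = " | "), " |"),
    paste0("|---|", paste(rep("---|", nrow(s)), collapse = "")),
    paste0("| Expenditure (total) | ", paste(fm(s$expenditure_total), collapse = " | "), " |"),
    paste0("| Benefit (GMB, total) | ", paste(fm(s$gross_benefit_total), collapse = " | "), " |"),
    paste0("| NMB (benefit - expenditure, total) | ", paste(fm(s$nmb_total), collapse = " | "), " |"),
    paste0("| Expenditure + highest NMB forgone | ",
           paste(ifelse(is.na(s$expenditure_plus_highest_forgone_nmb), "-",
                        fm(s$expenditure_plus_highest_forgone_nmb)), collapse = " | "), " |"),
    "",
    sprintf("Optimal option: %s. Chosen option (%s) is %soptimal; recommended methodology: %s.",
            a$optimal_id, a$chosen_id, if (a$chosen_is_optimal) "" else "not ",
            a$recommended_methodology),
    if (is.na(a$true_opportunity_cost)) {
      "True opportunity cost: not defined (no alternative use available)."
    } else {
      sprintf("True opportunity cost: %s", fm(a$true_opportunity_cost))
    }
  )
  lines
}

report_table <- function(results, assessment, currency) {
  vals <- rendered_values(results, currency)
  id_w <- max(nchar(results$approach_id), 8)
  desc_w <- max(nchar(results$description))
  lines <- character(0)
  for (m in intersect(c("A", "B", "C", "D"), results$methodology)) {
    lines <- c(lines, .oc_methodology_titles[[m]])
    idx <- which(results$methodology == m)
    lines <- c(lines, sprintf("  %-*s  %-*s  %s", id_w, results$approach_id[idx],
                              desc_w, results$description[idx], vals[idx]))
  }
  if (!is.null(assessment)) {
    md <- assessment_markdown(assessment, currency)
    md <- md[!grepl("^\\|?[-|]+$", md)] # markdown separator rows have no plain-text shape
    lines <- c(lines, "", gsub("^\\| |\\|$| \\|$", "", gsub(" \\| ", "  ", md)))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

report_csv <- function(results, assessment) {
  out <- readr::format_csv(as_tibble(results)[, c("approach_id", "methodology",
                                                  "unit", "value", "secondary_value",
                                                  "description")])
  if (!is.null(assessment)) {
    out <- paste0(out, "\n", readr::format_csv(assessment$assessments))
  }
  out
}

report_json <- function(results, assessment) {
  payload <- list(results = as_tibble(results)[, c("approach_id", "methodology",
                                                   "unit", "value", "secondary_value",
                                                   "description")])
  payload$chosen_id <- attr(results, "chosen_id")
  payload$second_best <- attr(results, "second_best")
  if (!is.null(assessment)) {
    payload$assessment <- list(
      options = assessment$assessments,
      optimal_id = assessment$optimal_id,
      chosen_is_optimal = assessment$chosen_is_optimal,
      recommended_methodology = assessment$recommended_methodology,
      true_opportunity_cost = assessment$true_opportunity_cost
    )
  }
  paste0(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                          pretty = TRUE), "\n")
}
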