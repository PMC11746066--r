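#' Read a parameter from a model specification by id
#'
#' Parameter ids are dotted paths mirroring the specification sections, e.g.
#' `"drugs.imatinib.ccyr"`, `"costs.monitoring"`, `"utilities.u_apbp"`,
#' `"transplant.os_y1"`, `"econ.discount_rate"`. Adverse-event per-event
#' costs use `"costs.ae.<name>"` and incidences
#' `"costs.ae.<name>.incidence"`.
#'
#' @param spec A `tki_spec`.
#' @param id Parameter id (dotted path).
#' @return The scalar parameter value.
#' @examples
#' spec_get(builtin_basecase(), "drugs.imatinib.ccyr")
#' @export
spec_get <- function(spec, id) {
  loc <- locate_param(spec, id)
  loc$get()
}

#' Set a parameter in a model specification by id
#'
#' Returns a modified copy; the input specification is untouched.
#'
#' @inheritParams spec_get
#' @param value New scalar value.
#' @return A `tki_spec` with the parameter replaced.
#' @examples
#' s <- spec_set(builtin_basecase(), "econ.discount_rate", 0)
#' s$econ$discount_rate
#' @export
spec_set <- function(spec, id, value) {
  loc <- locate_param(spec, id)
  loc$set(value)
}

locate_param <- function(spec, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) >= 2 && parts[1] == "costs" && parts[2] == "ae") {
    if (length(parts) < 3) stop("unknown parameter id: ", id)
    ae_name <- parts[3]
    field <- if (length(parts) >= 4) parts[4] else "cost"
    idx <- which(vapply(spec$costs$adverse_events, function(a) a$name,
                        character(1)) == ae_name)
    if (length(idx) != 1 || !field %in% c("cost", "incidence"))
      stop("unknown parameter id: ", id)
    return(list(
      get = function() spec$costs$adverse_events[[idx]][[field]],
      set = function(v) {
        spec$costs$adverse_events[[idx]][[field]] <- v
        spec
      }
    ))
  }
  node <- spec
  for (p in parts[-length(parts)]) {
    if (is.null(node[[p]])) stop("unknown parameter id: ", id)
    node <- node[[p]]
  }
  leaf <- parts[length(parts)]
  if (is.null(node[[leaf]]) || !is.numeric(node[[leaf]]))
    stop("unknown parameter id: ", id)
  list(
    get = function() node[[leaf]],
    set = function(v) {
      spec[[parts]] <- v
      spec
    }
  )
}

#' Look up the sensitivity range of a parameter
#'
#' @inheritParams spec_get
#' @return One-row data frame with columns `id`, `low`, `high`, `family`, or
#'   `NULL` if the parameter has no range.
#' @export
spec_range <- function(spec, id) {
  hit <- spec$ranges[spec$ranges$id == id, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit
}

#' Default range for a parameter lacking printed bounds
#'
#' Applies the fallback rule used for one-way sensitivity analysis when no
#' interval is available: plus/minus 50\% of the base value, with
#' probabilities and utilities capped to \[0,1\].
#'
#' @inheritParams spec_get
#' @param family Distribution family for the parameter class: `"beta"` for
#'   probabilities/utilities, `"gamma"` for costs.
#' @return One-row range data frame.
#' @export
default_range <- function(spec, id, family = c("gamma", "beta")) {
  family <- match.arg(family)
  base <- spec_get(spec, id)
  low <- base * 0.5
  high <- base * 1.5
  if (family == "beta") {
    low <- max(0, low)
    high <- min(1, high)
  }
  range_row(id, low, high, family)
}

# ---- config file IO --------------------------------------------------------

#' Write a model specification to a YAML config file
#'
#' The file mirrors the specification sections (`drugs`, `strategies`,
#' `transplant`, `apbp`, `costs`, `utilities`, `econ`, `conventions`,
#' `ranges`) and can be re-read with [load_config()]; a written-and-reloaded
#' specification is identical to machine precision.
#'
#' @param spec A `tki_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, path) {
  x <- unclass(spec)
  x$ranges <- lapply(seq_len(nrow(spec$ranges)), function(i)
    as.list(spec$ranges[i, ]))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Load a model specification from a YAML config file
#'
#' Any field omitted from the file takes its value from
#' [builtin_basecase()]; fields present override the base case. Named
#' sections are merged recursively; the list-valued sections
#' `costs$adverse_events`, `ranges` and each strategy's `switch` map are
#' replaced wholesale when present. Unknown keys are an error (the message
#' lists the valid keys at that level). If the file sets
#' `econ$gdp_per_capita` without setting `econ$wtp`, the willingness-to-pay
#' threshold is re-derived as `wtp_multiplier` times GDP per capita, rounded
#' to the nearest 10 US$.
#'
#' @param path Path to a YAML config file.
#' @param base Specification supplying defaults (default
#'   [builtin_basecase()]).
#' @return A validated `tki_spec`.
#' @export
load_config <- function(path, base = builtin_basecase()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("configuration parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping")

  spec <- merge_config(base, raw)

  wtp_set <- !is.null(raw$econ) && !is.null(raw$econ$wtp)
  gdp_set <- !is.null(raw$econ) && !is.null(raw$econ$gdp_per_capita)
  if (gdp_set && !wtp_set) {
    spec$econ$wtp <- derive_wtp(spec$econ$gdp_per_capita,
                                spec$econ$wtp_multiplier)$value
  }

  issues <- validate_spec(spec)
  if (length(issues) > 0)
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  spec
}

merge_config <- function(base, override) {
  spec <- unclass(base)
  check_keys(names(override), names(spec), "top level")
  for (sect in names(override)) {
    val <- override[[sect]]
    if (sect == "ranges") {
      spec$ranges <- do.call(rbind, lapply(val, function(r) {
        check_keys(names(r), c("id", "low", "high", "family"), "ranges entry")
        range_row(r$id, r$low, r$high, r$family)
      }))
    } else if (sect %in% c("drugs", "strategies")) {
      for (nm in names(val)) {
        cur <- spec[[sect]][[nm]]
        if (is.null(cur)) cur <- list(name = nm)
        valid <- if (sect == "drugs") c("name", DRUG_FIELDS) else
          c("name", "first_line", "switch")
        check_keys(names(val[[nm]]), valid, paste0(sect, ".", nm))
        cur <- modifyList(cur, val[[nm]])
        cur$name <- nm
        spec[[sect]][[nm]] <- cur
      }
    } else if (sect == "costs") {
      check_keys(names(val), c("consult", "monitoring", "adverse_events"),
                 "costs")
      if (!is.null(val$adverse_events)) {
        spec$costs$adverse_events <- lapply(val$adverse_events, function(a) {
          check_keys(names(a), c("name", "cost", "incidence"),
                     "adverse_events entry")
          a
        })
        val$adverse_events <- NULL
      }
      spec$costs <- modifyList(spec$costs, val)
    } else if (is.list(spec[[sect]])) {
      check_keys(names(val), names(spec[[sect]]), sect)
      spec[[sect]] <- modifyList(spec[[sect]], val)
    } else {
      spec[[sect]] <- val
    }
  }
  new_tki_spec(spec)
}

check_keys <- function(got, valid, where) {
  bad <- setdiff(got, valid)
  if (length(bad) > 0)
    stop(sprintf("unknown key(s) %s at %s; valid keys: %s",
                 paste0("'", bad, "'", collapse = ", "), where,
                 paste(valid, collapse = ", ")), call. = FALSE)
}
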