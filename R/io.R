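# Plain-text I/O: the DATAB.txt parameter-file dialect, RESB.txt-style
# result reports, delimited trajectory exports, scenario config files and
# observed-data tables.

.datab_fields1 <- c("na0", "k0", "cl0", "B0", "kv",
                    "na", "k", "cl", "beta", "gamma")
.datab_fields2 <- c("pna", "pk", "pcl", "inc", "ikc", "inkcc", "hp", "kb")

#' Read a DATAB.txt parameter file
#'
#' Parses the two-record plain-text parameter layout: record 1 holds
#' `na0 k0 cl0 B0 kv na k cl beta gamma` and record 2
#' `pna pk pcl inc ikc inkcc hp kb`. Fields are whitespace- or
#' newline-separated; scientific notation (`3E-5`) is accepted; lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return A list with `medium` (an [external_medium()]), `na`, `k`, `cl`
#'   (initial intracellular concentrations, mM), `params`
#'   (a [membrane_params()]) and `hp`.
#' @examples
#' path <- system.file("extdata", "table2_datab.txt", package = "pumpleak")
#' read_datab(path)
#' @export
read_datab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- unlist(strsplit(paste(lines, collapse = " "), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  fields <- c(.datab_fields1, .datab_fields2)
  if (length(tokens) != length(fields))
    stop(sprintf("expected %d fields (%d + %d per record), found %d in %s",
                 length(fields), length(.datab_fields1),
                 length(.datab_fields2), length(tokens), path))
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("field '%s' (position %d) is not numeric: '%s'",
                 fields[bad], bad, tokens[bad]))
  }
  names(vals) <- fields
  rates <- vals[c("beta", "gamma", "pna", "pk", "pcl",
                  "inc", "ikc", "inkcc", "kb")]
  if (any(rates < 0)) {
    bad <- names(rates)[which(rates < 0)[1]]
    stop(sprintf("rate coefficient '%s' is negative: %g", bad, vals[[bad]]))
  }
  list(medium = external_medium(vals[["na0"]], vals[["k0"]], vals[["cl0"]],
                                b0 = vals[["B0"]], kv = vals[["kv"]]),
       na = vals[["na"]], k = vals[["k"]], cl = vals[["cl"]],
       params = membrane_params(beta = vals[["beta"]],
                                gamma = vals[["gamma"]],
                                pna = vals[["pna"]], pk = vals[["pk"]],
                                pcl = vals[["pcl"]], inc = vals[["inc"]],
                                ikc = vals[["ikc"]],
                                inkcc = vals[["inkcc"]],
                                kb = vals[["kb"]]),
       hp = as.integer(vals[["hp"]]))
}

#' Write a DATAB.txt parameter file
#'
#' Inverse of [read_datab()]: writes the two whitespace-separated records
#' with full (15 significant digit) precision, plus a comment line naming
#' the fields of each record.
#'
#' @param x A list as returned by [read_datab()], or a [scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_datab <- function(x, path) {
  if (inherits(x, "scenario"))
    x <- list(medium = x$medium, na = x$na, k = x$k, cl = x$cl,
              params = x$params, hp = x$hp)
  m <- x$medium; p <- x$params
  fmt <- function(v) paste(vapply(v, format, character(1), digits = 15),
                           collapse = " ")
  lines <- c(paste("#", paste(.datab_fields1, collapse = " ")),
             fmt(c(m$na0, m$k0, m$cl0, m$b0, m$kv, x$na, x$k, x$cl,
                   p$beta, p$gamma)),
             paste("#", paste(.datab_fields2, collapse = " ")),
             fmt(c(p$pna, p$pk, p$pcl, p$inc, p$ikc, p$inkcc, x$hp, p$kb)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a RESB.txt-style result report
#'
#' Emits the three-section plain-text report of a finished run: (A) the
#' sampled time course of variables, (B) an echo of the parameter values,
#' and (C) the net/influx/efflux flux decomposition at the final time,
#' followed by `z`, `OSOR` and `A/V*1000`. With `csv_path`, the full time
#' course is additionally exported as a machine-readable CSV.
#'
#' @param timecourse A [simulate_cell()] result.
#' @param path Report file path.
#' @param scn The [scenario()] that produced the run (parameter echo);
#'   optional.
#' @param csv_path Optional path for the delimited trajectory export.
#' @return `path`, invisibly.
#' @examples
#' scn <- fixture_scenario("table2_balance")
#' tc <- simulate_cell(scn, hp = 2400)
#' rpt <- tempfile(fileext = ".txt")
#' write_resb(tc, rpt, scn = scn)
#' cat(readLines(rpt, n = 8), sep = "\n")
#' @export
write_resb <- function(timecourse, path, scn = NULL, csv_path = NULL) {
  if (nrow(timecourse) == 0) stop("empty time course")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)

  w("(A) TIME COURSE OF VARIABLES")
  w("# t min; U mV; na k cl mM; V ml/mmol A; mun muk mucl mV; prna prk prcl mM/min")
  df <- as.data.frame(timecourse)[, c("t", "U", "na", "k", "cl", "V",
                                      "mun", "muk", "mucl",
                                      "prna", "prk", "prcl")]
  w(paste(names(df), collapse = "\t"))
  for (i in seq_len(nrow(df)))
    w(paste(vapply(df[i, ], function(v) format(v, digits = 6),
                   character(1)), collapse = "\t"))

  w("")
  w("(B) PARAMETER VALUES")
  if (!is.null(scn)) {
    m <- scn$medium; p <- scn$params
    w("na0 k0 cl0 B0 kv na k cl beta gamma  # mM; kv dimensionless; beta 1/min")
    w(paste(format(c(m$na0, m$k0, m$cl0, m$b0, m$kv, scn$na, scn$k, scn$cl,
                     p$beta, p$gamma), digits = 10), collapse = " "))
    w("pna pk pcl inc ikc inkcc hp kb  # 1/min; ml/umol/min; ml^3/umol^3/min")
    w(paste(format(c(p$pna, p$pk, p$pcl, p$inc, p$ikc, p$inkcc, scn$hp,
                     p$kb), digits = 10), collapse = " "))
    if (!is.null(scn$schedule)) {
      for (i in seq_along(scn$schedule$times)) {
        ov <- scn$schedule$overrides[[i]]
        w("at t=%g min: %s", scn$schedule$times[i],
          paste(names(ov), unlist(ov), sep = "=", collapse = " "))
      }
    }
  } else w("(scenario not supplied)")

  w("")
  w("(C) FLUX BALANCE AT THE FINAL TIME POINT")
  w("# umol min^-1 (ml cell water)^-1; outward net fluxes negative")
  ft <- flux_table_at(timecourse, nrow(timecourse))
  section <- function(title, mat, cols) {
    w(paste(c(title, cols), collapse = "\t"))
    for (ion in rownames(mat))
      w(paste(c(ion, format(mat[ion, ], digits = 6)), collapse = "\t"))
  }
  section("Net flux", ft$net, colnames(ft$net))
  section("Influx", ft$influx, paste0("I", colnames(ft$influx)))
  section("Efflux", ft$efflux, paste0("E", colnames(ft$efflux)))

  osor <- tryCatch(compute_osor(ft), error = function(e) NA_real_)
  w("")
  w("z\tOSOR\tA/V*1000")
  w("%s\t%s\t%s", format(attr(timecourse, "z"), digits = 6),
    if (is.na(osor)) "undefined (no ouabain-resistant K influx)"
    else format(osor, digits = 6),
    format(1000 / timecourse$V[nrow(timecourse)], digits = 6))
  w("# OSOR denominator includes K influx via channels, KC and NKCC")

  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(timecourse), csv_path, row.names = FALSE)
  invisible(path)
}

# flux table attached to sample row i of a time course
flux_table_at <- function(timecourse, i) {
  ft <- attr(timecourse, "flux_tables")
  if (is.null(ft) || is.null(ft[[i]]))
    stop("time course was run with record_fluxes = FALSE")
  ft[[i]]
}

#' Read an observed ion time-course table
#'
#' Reads a delimited text table with columns `t`, `na`, `k`, `cl`
#' (header required; comma, tab or whitespace separated).
#'
#' @param path File path.
#' @return A data.frame suitable for [sse_objective()] /
#'   [fit_parameters()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first))
    utils::read.csv(path, comment.char = "#")
  else utils::read.table(path, header = TRUE, comment.char = "#")
  validate_observations(df)
}

#' Read a scenario config file
#'
#' A documented key-value format: one `key value` (or `key = value`) pair
#' per line for the medium (`na0 k0 cl0 b0 kv`), initial concentrations
#' (`na k cl`), transport parameters (`beta gamma pna pk pcl inc ikc inkcc
#' kb`) and run settings (`t_end dt hp label`); schedule events as
#' `at <time> <name>=<value> ...` lines; `#` comments.
#'
#' @param path File path.
#' @return A [scenario()].
#' @examples
#' p <- tempfile()
#' writeLines(c("na0 140", "k0 5.8", "cl0 116", "b0 48.2",
#'              "na 32", "k 117", "cl 40",
#'              "beta 0.029", "pna 0.0041", "pk 0.0115", "pcl 0.0125",
#'              "inc 3e-6", "t_end 240",
#'              "at 0 pk=0.03 pna=0.003 pcl=0.068 kb=0.000068",
#'              "at 30 pk=0.02"), p)
#' read_scenario(p)
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  ev_times <- numeric()
  ev_ov <- list()
  for (ln in lines) {
    if (grepl("^at\\s", ln)) {
      parts <- strsplit(trimws(sub("^at\\s+", "", ln)), "\\s+")[[1]]
      tt <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(tt)) stop("bad schedule line: ", ln)
      ov <- list()
      for (pp in parts[-1]) {
        eq <- strsplit(pp, "=", fixed = TRUE)[[1]]
        if (length(eq) != 2) stop("bad override '", pp, "' in: ", ln)
        ov[[eq[1]]] <- as.numeric(eq[2])
      }
      ev_times <- c(ev_times, tt)
      ev_ov <- c(ev_ov, list(ov))
    } else {
      parts <- strsplit(gsub("=", " ", ln), "\\s+")[[1]]
      if (length(parts) != 2) stop("bad config line: ", ln)
      kv[[parts[1]]] <- parts[2]
    }
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) {
      if (is.null(default)) stop("missing required key: ", key)
      return(default)
    }
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("non-numeric value for key '", key, "'")
    v
  }
  sched <- if (length(ev_times)) {
    o <- order(ev_times)
    param_schedule(ev_times[o], ev_ov[o])
  } else NULL
  scenario(
    external_medium(num("na0"), num("k0"), num("cl0"),
                    b0 = num("b0", 0), kv = num("kv", 1)),
    membrane_params(beta = num("beta", 0), gamma = num("gamma", 1.5),
                    pna = num("pna", 0), pk = num("pk", 0),
                    pcl = num("pcl", 0), inc = num("inc", 0),
                    ikc = num("ikc", 0), inkcc = num("inkcc", 0),
                    kb = num("kb", 0)),
    na = num("na"), k = num("k"), cl = num("cl"),
    schedule = sched,
    t_end = num("t_end", 240), dt = num("dt", 0.01),
    hp = num("hp", 100), label = kv[["label"]])
}
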