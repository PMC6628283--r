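#' Read a delimited clinical dataset
#'
#' Reads a header-first delimited text file (delimiter auto-detected among
#' comma, semicolon and tab, or forced via `delim`), types every column as
#' numeric, and encodes non-numeric (nominal) columns as integer codes in
#' first-appearance order, recording the code book. Cells equal to
#' `missing_token` become `NA`, to be imputed by [preprocess()].
#'
#' @param path Path to the file.
#' @param delim Optional delimiter; default auto-detect.
#' @param missing_token Text marking a missing cell (default `"?"`).
#' @param nominal Optional character vector of column names to force-treat as
#'   nominal. Columns not listed are numeric when every non-missing cell
#'   parses as a number, nominal when none does; a mixed column is an error.
#' @return A tibble of numeric columns with attributes `codebook` (named list
#'   mapping codes to original category strings, for nominal columns) and
#'   `missing_token`.
#' @export
read_dataset <- function(path, delim = NULL, missing_token = "?",
                         nominal = character()) {
  if (!file.exists(path)) rlang::abort(sprintf("file '%s' not found", path))
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    counts <- vapply(c(",", ";", "\t"), function(d) {
      length(strsplit(header, d, fixed = TRUE)[[1]])
    }, integer(1))
    delim <- names(counts)[which.max(counts)]
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), trim_ws = TRUE,
    progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) rlang::abort("empty dataset (header only)")

  codebook <- list()
  out <- purrr::imap(raw, function(col, nm) {
    col[col == missing_token] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    parsed <- !is.na(num) | is.na(col)
    if (all(parsed) && !nm %in% nominal) return(num)
    if (any(parsed & !is.na(col)) && !nm %in% nominal) {
      rlang::abort(sprintf(
        "column '%s' mixes numeric cells with unparseable text (not the missing token)",
        nm))
    }
    # nominal column: codes assigned in first-appearance order
    lev <- unique(col[!is.na(col)])
    codebook[[nm]] <<- stats::setNames(lev, seq_along(lev))
    as.numeric(match(col, lev))
  })
  res <- tibble::as_tibble(out)
  attr(res, "codebook") <- codebook
  attr(res, "missing_token") <- missing_token
  res
}

#' Preprocess a dataset
#'
#' Replaces missing cells (read in as `NA` from the missing token) with a
#' fixed imputation value — 0 by default, which lies outside the usual 1-10
#' clinical code range and therefore forms its own low cluster — and applies
#' per-column recodes such as mapping a class coded 2/4 onto 1/2.
#' Idempotent: preprocessing an already-clean table is a no-op.
#'
#' @param data Data frame from [read_dataset()] (or any numeric data frame).
#' @param impute Value substituted for missing cells.
#' @param recode Named list: for column `nm`, a named numeric vector mapping
#'   old values (names) to new values, e.g. `list(Class = c("2" = 1, "4" = 2))`.
#' @return A tibble with no missing cells, same rows, attributes preserved.
#' @export
preprocess <- function(data, impute = 0, recode = list()) {
  res <- tibble::as_tibble(data)
  for (nm in names(res)) {
    col <- res[[nm]]
    col[is.na(col)] <- impute
    if (nm %in% names(recode)) {
      map <- recode[[nm]]
      old <- as.numeric(names(map))
      missing_targets <- setdiff(old, unique(col))
      if (length(missing_targets)) {
        rlang::warn(sprintf(
          "recode for '%s' references value(s) %s absent from the column",
          nm, paste(missing_targets, collapse = ", ")))
      }
      hit <- match(col, old)
      col[!is.na(hit)] <- as.numeric(map)[hit[!is.na(hit)]]
    }
    res[[nm]] <- col
  }
  for (a in c("codebook", "missing_token")) {
    attr(res, a) <- attr(data, a, exact = TRUE)
  }
  res
}

fmt_num <- function(x) sprintf("%.15g", x)

fis_var_block <- function(v, header) {
  lines <- c(
    sprintf("[%s]", header),
    sprintf("Name='%s'", v$name),
    sprintf("Range=[%s %s]", fmt_num(v$range[1]), fmt_num(v$range[2])),
    sprintf("NumMFs=%d", length(v$mfs))
  )
  for (i in seq_along(v$mfs)) {
    m <- v$mfs[[i]]
    lines <- c(lines, sprintf("MF%d='%s':'%s',[%s]", i, m$label, m$shape,
                              paste(fmt_num(m$params), collapse = " ")))
  }
  lines
}

#' Write a fuzzy system to a `.fis` text file
#'
#' Serialises the system in the de-facto fuzzy-toolbox text dialect: a
#' `[System]` block, one `[InputN]`/`[OutputN]` block per variable (each MF as
#' `'label':'trimf'/'trapmf',[params]`), and a `[Rules]` block whose lines list
#' antecedent indices, a comma, consequent indices, the weight in parentheses
#' and the connector code (1 = AND, 2 = OR); 0 marks an input a rule does not
#' use. The formatting is canonical: write-read-write is byte-stable.
#'
#' @param system An [fz_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fis <- function(system, path) {
  stopifnot(inherits(system, "fz_system"))
  rm <- rule_matrices(system)
  lines <- c(
    "[System]",
    sprintf("Name='%s'", system$name),
    "Type='mamdani'",
    "Version=2.0",
    sprintf("NumInputs=%d", length(system$inputs)),
    sprintf("NumOutputs=%d", length(system$outputs)),
    sprintf("NumRules=%d", length(system$rules)),
    "AndMethod='min'",
    "OrMethod='max'",
    "ImpMethod='min'",
    "AggMethod='max'",
    sprintf("DefuzzMethod='%s'", system$defuzz_method)
  )
  for (i in seq_along(system$inputs)) {
    lines <- c(lines, "", fis_var_block(system$inputs[[i]], sprintf("Input%d", i)))
  }
  for (i in seq_along(system$outputs)) {
    lines <- c(lines, "", fis_var_block(system$outputs[[i]], sprintf("Output%d", i)))
  }
  lines <- c(lines, "", "[Rules]")
  for (r in seq_along(system$rules)) {
    lines <- c(lines, sprintf(
      "%s, %s (%s) : %d",
      paste(rm$ant[r, ], collapse = " "),
      paste(rm$cons[r, ], collapse = " "),
      fmt_num(rm$weight[r]),
      if (rm$connector[r] == "and") 1L else 2L
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

fis_error <- function(msg, lineno) {
  rlang::abort(sprintf("fis parse error at line %d: %s", lineno, msg))
}

parse_fis_field <- function(lines, key, lineno_base) {
  hit <- grep(sprintf("^%s=", key), lines)
  if (length(hit) == 0) {
    fis_error(sprintf("missing field '%s'", key), lineno_base)
  }
  sub(sprintf("^%s=", key), "", lines[hit[1]])
}

unquote <- function(x) gsub("^'|'$", "", x)

#' Read a fuzzy system from a `.fis` text file
#'
#' Parses the dialect written by [write_fis()] and reconstructs an
#' [fz_system()] whose inference matches the original. Unknown membership
#' shapes, out-of-range rule indices and malformed block headers raise errors
#' carrying the offending line number.
#'
#' @param path Path to a `.fis` file.
#' @param resolution Defuzzification grid size of the rebuilt system.
#' @return An [fz_system()].
#' @export
read_fis <- function(path, resolution = 1001L) {
  lines <- readLines(path)
  starts <- grep("^\\[.*\\]$", lines)
  if (length(starts) == 0) fis_error("no block headers found", 1L)
  headers <- gsub("^\\[|\\]$", "", lines[starts])
  bad <- grep("^(System|Input[0-9]+|Output[0-9]+|Rules)$", headers, invert = TRUE)
  if (length(bad)) {
    fis_error(sprintf("unknown block '[%s]'", headers[bad[1]]), starts[bad[1]])
  }
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- purrr::map2(starts, ends, function(s, e) {
    list(header = gsub("^\\[|\\]$", "", lines[s]),
         body = lines[seq(s, e)][-1], line = s)
  })
  names(blocks) <- vapply(blocks, `[[`, character(1), "header")

  sys_b <- blocks[["System"]]
  if (is.null(sys_b)) fis_error("missing [System] block", 1L)
  name <- unquote(parse_fis_field(sys_b$body, "Name", sys_b$line))
  n_in <- as.integer(parse_fis_field(sys_b$body, "NumInputs", sys_b$line))
  n_out <- as.integer(parse_fis_field(sys_b$body, "NumOutputs", sys_b$line))
  defuzz <- unquote(parse_fis_field(sys_b$body, "DefuzzMethod", sys_b$line))

  parse_var <- function(b) {
    vname <- unquote(parse_fis_field(b$body, "Name", b$line))
    range <- as.numeric(strsplit(
      gsub("^\\[|\\]$", "", parse_fis_field(b$body, "Range", b$line)), " +")[[1]])
    n_mfs <- as.integer(parse_fis_field(b$body, "NumMFs", b$line))
    mfs <- lapply(seq_len(n_mfs), function(i) {
      ln <- grep(sprintf("^MF%d=", i), b$body)
      if (length(ln) == 0) fis_error(sprintf("missing MF%d", i), b$line)
      spec <- sub(sprintf("^MF%d=", i), "", b$body[ln[1]])
      parts <- strsplit(spec, ",\\[")[[1]]
      lab_shape <- strsplit(parts[1], ":")[[1]]
      shape <- unquote(lab_shape[2])
      params <- as.numeric(strsplit(gsub("\\]$", "", parts[2]), " +")[[1]])
      if (shape == "trimf") {
        fz_trimf(params[1], params[2], params[3], label = unquote(lab_shape[1]))
      } else if (shape == "trapmf") {
        fz_trapmf(params[1], params[2], params[3], params[4],
                  label = unquote(lab_shape[1]))
      } else {
        fis_error(sprintf("unknown membership shape '%s'", shape), b$line + ln[1])
      }
    })
    fz_variable(vname, range[1], range[2], mfs)
  }

  inputs <- lapply(seq_len(n_in), function(i) {
    b <- blocks[[sprintf("Input%d", i)]]
    if (is.null(b)) fis_error(sprintf("missing [Input%d] block", i), 1L)
    parse_var(b)
  })
  outputs <- lapply(seq_len(n_out), function(i) {
    b <- blocks[[sprintf("Output%d", i)]]
    if (is.null(b)) fis_error(sprintf("missing [Output%d] block", i), 1L)
    parse_var(b)
  })

  rules_b <- blocks[["Rules"]]
  if (is.null(rules_b)) fis_error("missing [Rules] block", length(lines))
  rule_lines <- rules_b$body[nzchar(trimws(rules_b$body))]
  n_mfs_in <- vapply(inputs, function(v) length(v$mfs), integer(1))
  n_mfs_out <- vapply(outputs, function(v) length(v$mfs), integer(1))
  rules <- lapply(seq_along(rule_lines), function(i) {
    ln <- rules_b$line + i
    m <- regmatches(rule_lines[i],
                    regexec("^([-0-9 ]+), *([-0-9 ]+) *\\(([^)]+)\\) *: *([12])$",
                            rule_lines[i]))[[1]]
    if (length(m) != 5) fis_error("malformed rule line", ln)
    ant <- as.integer(strsplit(trimws(m[2]), " +")[[1]])
    cons <- as.integer(strsplit(trimws(m[3]), " +")[[1]])
    if (length(ant) != n_in || length(cons) != n_out) {
      fis_error("rule arity does not match the declared variables", ln)
    }
    if (any(ant > n_mfs_in) || any(cons > n_mfs_out)) {
      fis_error("rule references a membership function index out of range", ln)
    }
    fz_rule(ant, cons, weight = as.numeric(m[4]),
            connector = if (m[5] == "1") "and" else "or")
  })
  fz_system(inputs, outputs, rules, name = name,
            defuzz_method = defuzz, resolution = resolution)
}

#' Write a search report
#'
#' Writes the evaluated candidates of a search as a delimited table:
#' provenance columns (iteration, features, cluster counts, rule count,
#' partition, seed) followed by the metric columns. For a cross-validation
#' search each candidate contributes one row per fold plus a `mean` row; for
#' random sampling, one row per candidate.
#'
#' @param search An [fis_search()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(search, path) {
  stopifnot(inherits(search, "fz_search"))
  res <- search$results
  if (nrow(res) == 0) rlang::abort("no results to report")
  cv <- search$control$partition == "cross_validation"
  rows <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
    base <- tibble::tibble(
      rank = res$rank[i], iteration = res$iteration[i],
      features = res$features[i], ks = res$ks[i],
      partition = search$control$partition, seed = search$seed
    )
    fm <- res$fold_metrics[[i]]
    if (cv) {
      mean_row <- fm |>
        dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
        dplyr::mutate(fold = NA_integer_)
      fm <- dplyr::bind_rows(fm, mean_row)
      fm$fold <- c(as.character(fm$fold[-nrow(fm)]), "mean")
    } else {
      fm$fold <- NULL
    }
    dplyr::bind_cols(base[rep(1, nrow(fm)), ], fm)
  })
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
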