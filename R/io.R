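#' Read and write per-nucleotide cleavage profiles
#'
#' Tab-delimited text with columns `position`, `plus`, `minus`
#' (1-based positions; comment lines start with `#`). Masked positions
#' are written with the `-999` sentinel in both channels.
#'
#' @param profile A `cleavage_profile`.
#' @param path File path.
#' @return `read_cleavage_profile()` returns a `cleavage_profile`;
#'   the writer returns `path` invisibly.
#' @export
write_cleavage_profile <- function(profile, path) {
  out <- tibble(position = profile$position,
                plus = ifelse(profile$masked, -999, profile$plus),
                minus = ifelse(profile$masked, -999, profile$minus))
  writeLines("# cleavage profile; 1-based positions; -999 = no data", path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cleavage_profile
#' @export
read_cleavage_profile <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  masked <- d$plus == -999 | d$minus == -999
  new_cleavage_profile(
    tibble(position = as.integer(d$position),
           plus = ifelse(masked, NA_real_, d$plus),
           minus = ifelse(masked, NA_real_, d$minus),
           masked = masked))
}

#' Read and write normalized reactivity profiles (SHAPE-style)
#'
#' Two-column tab-delimited `position`, `reactivity` with the
#' conventional `-999` sentinel for positions with no data.
#'
#' @param profile A `reactivity_profile`.
#' @param path File path.
#' @return `read_reactivity()` returns a `reactivity_profile`; the writer
#'   returns `path` invisibly.
#' @export
write_reactivity <- function(profile, path) {
  out <- tibble(position = profile$position,
                reactivity = ifelse(profile$masked | is.na(profile$reactivity),
                                    -999, profile$reactivity))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_reactivity
#' @export
read_reactivity <- function(path) {
  d <- readr::read_tsv(path, col_names = c("position", "reactivity"),
                       comment = "#", show_col_types = FALSE)
  masked <- d$reactivity == -999
  new_reactivity_profile(as.integer(d$position),
                         ifelse(masked, NA_real_, d$reactivity),
                         masked, normalization_factor = NA_real_)
}

#' Write an RNA structure as a CT file (plus annotation side-cars)
#'
#' Standard 6-column connectivity table: index, base, 5' connect,
#' 3' connect, pairing partner (0 = unpaired), natural numbering.
#' When `sidecar = TRUE`, element annotations are written to
#' `<path>.elements.tsv` (label, kind, start, end; one row per contiguous
#' segment) and tetraloop-receptor contacts to `<path>.contacts.tsv`
#' (comma-joined position lists).
#'
#' @param model An [rna_structure()].
#' @param path CT file path.
#' @param sidecar Write the annotation side-car tables too?
#' @return `path`, invisibly.
#' @export
write_ct <- function(model, path, sidecar = TRUE) {
  L <- model$length
  partner <- integer(L)
  if (nrow(model$pairs) > 0) {
    partner[model$pairs$i] <- model$pairs$j
    partner[model$pairs$j] <- model$pairs$i
  }
  lines <- c(sprintf("%d %s", L, model$name),
             sprintf("%d %s %d %d %d %d", seq_len(L), model$sequence,
                     seq_len(L) - 1L, c(seq_len(L - 1L) + 1L, 0L),
                     partner, seq_len(L)))
  writeLines(lines, path)
  if (sidecar) {
    write_structure_sidecars(model, path)
  }
  invisible(path)
}

segments_of <- function(pos) {
  pos <- sort(pos)
  brk <- c(0, which(diff(pos) > 1), length(pos))
  purrr::map_dfr(seq_len(length(brk) - 1), function(k) {
    seg <- pos[(brk[k] + 1):brk[k + 1]]
    tibble(start = seg[1], end = seg[length(seg)])
  })
}

write_structure_sidecars <- function(model, path) {
  el <- purrr::map_dfr(seq_len(nrow(model$elements)), function(k) {
    dplyr::mutate(segments_of(model$elements$positions[[k]]),
                  label = model$elements$label[k],
                  kind = model$elements$kind[k], .before = 1)
  })
  readr::write_tsv(el, paste0(path, ".elements.tsv"))
  ct <- model$contacts
  if (nrow(ct) > 0) {
    joined <- tibble(
      loop = ct$loop, receptor = ct$receptor,
      loop_positions = purrr::map_chr(ct$loop_positions, paste, collapse = ","),
      receptor_positions = purrr::map_chr(ct$receptor_positions, paste, collapse = ","),
      extension_positions = purrr::map_chr(ct$extension_positions, paste, collapse = ","))
    readr::write_tsv(joined, paste0(path, ".contacts.tsv"))
  }
  invisible(path)
}

#' Read an RNA structure from a CT file
#'
#' Parses a standard connectivity table, validating that pairing is
#' symmetric (an `i -> j` row whose partner row does not point back at
#' `i` is a parse failure naming the offending row). Side-car annotation
#' tables written by [write_ct()] are picked up automatically when
#' present.
#'
#' @param path CT file path.
#' @return An [rna_structure()].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(L)) abort("malformed CT header: first field must be the length")
  name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else "ct"
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != L) {
    abort(sprintf("CT body has %d rows but header declares %d", length(body), L))
  }
  seqv <- character(L)
  partner <- integer(L)
  for (r in seq_along(body)) {
    f <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(f) < 5) abort(sprintf("malformed CT row %d: fewer than 5 fields", r))
    i <- suppressWarnings(as.integer(f[1]))
    pj <- suppressWarnings(as.integer(f[5]))
    if (is.na(i) || is.na(pj) || i != r) {
      abort(sprintf("malformed CT row %d: bad index or pairing field", r))
    }
    seqv[i] <- f[2]
    partner[i] <- pj
  }
  for (i in seq_len(L)) {
    j <- partner[i]
    if (j != 0 && (j < 1 || j > L || partner[j] != i)) {
      abort(sprintf("inconsistent pairing at CT row %d: %d -> %d but %d -> %d",
                    i, i, j, j, if (j >= 1 && j <= L) partner[j] else NA_integer_))
    }
  }
  keep <- partner != 0 & seq_len(L) < partner
  pairs <- tibble(i = which(keep), j = partner[keep])

  elements <- contacts <- NULL
  el_path <- paste0(path, ".elements.tsv")
  if (file.exists(el_path)) {
    seg <- readr::read_tsv(el_path, show_col_types = FALSE)
    elements <- seg |>
      dplyr::group_by(.data$label, .data$kind) |>
      dplyr::summarise(positions = list(unlist(purrr::map2(.data$start, .data$end, seq))),
                       .groups = "drop")
  }
  ct_path <- paste0(path, ".contacts.tsv")
  if (file.exists(ct_path)) {
    cj <- readr::read_tsv(ct_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    parse_pos <- function(s) as.integer(strsplit(s, ",")[[1]])
    contacts <- tibble(
      loop = cj$loop, receptor = cj$receptor,
      loop_positions = purrr::map(cj$loop_positions, parse_pos),
      receptor_positions = purrr::map(cj$receptor_positions, parse_pos),
      extension_positions = purrr::map(cj$extension_positions, parse_pos))
  }
  rna_structure(name, seqv, pairs, elements, contacts)
}

#' Dot-bracket notation for nested secondary structures
#'
#' `parse_dotbracket()` turns a sequence/structure string pair into an
#' [rna_structure()]; `format_dotbracket()` renders a model's (nested)
#' pairing as a dot-bracket string. `read_dotbracket()`/
#' `write_dotbracket()` use a simple three-line file format:
#' `>name`, sequence, structure.
#'
#' @param sequence RNA sequence string.
#' @param structure Dot-bracket string of equal length.
#' @param name Model name.
#' @param model An [rna_structure()] (pairing must be pseudoknot-free).
#' @param path File path.
#' @return An [rna_structure()], a string, or (for writers) `path`
#'   invisibly.
#' @export
parse_dotbracket <- function(sequence, structure, name = "dotbracket") {
  if (nchar(sequence) != nchar(structure)) {
    abort("sequence and structure must have equal length")
  }
  chars <- strsplit(structure, "")[[1]]
  stack <- integer()
  pi <- pj <- integer()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0) abort(sprintf("unbalanced ')' at position %d", k))
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, k)
      stack <- stack[-length(stack)]
    } else if (chars[k] != ".") {
      abort(sprintf("unsupported character '%s' at position %d", chars[k], k))
    }
  }
  if (length(stack) > 0) abort("unbalanced '(' in structure")
  rna_structure(name, sequence, tibble(i = pi, j = pj)[order(pi), ])
}

#' @rdname parse_dotbracket
#' @export
format_dotbracket <- function(model) {
  out <- rep(".", model$length)
  out[model$pairs$i] <- "("
  out[model$pairs$j] <- ")"
  paste(out, collapse = "")
}

#' @rdname parse_dotbracket
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "dotbracket"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  parse_dotbracket(lines[1], lines[2], name)
}

#' @rdname parse_dotbracket
#' @export
write_dotbracket <- function(model, path) {
  writeLines(c(paste0(">", model$name),
               paste(model$sequence, collapse = ""),
               format_dotbracket(model)), path)
  invisible(path)
}

#' Read a structure model from CT or dot-bracket
#'
#' Dispatches on file extension: `.ct` to [read_ct()], anything else to
#' [read_dotbracket()].
#'
#' @param path File path.
#' @return An [rna_structure()].
#' @export
read_structure <- function(path) {
  if (grepl("\\.ct$", path, ignore.case = TRUE)) read_ct(path)
  else read_dotbracket(path)
}

#' Read and write trace channels as plain text
#'
#' One tab-delimited file holding the shared elution axis and one column
#' per channel, plus a `# peak_positions:` header line so the expected
#' per-nucleotide peak centers survive the round trip.
#'
#' @param trace A `trace`.
#' @param path File path.
#' @return `read_trace()` returns a `trace`; the writer returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  hdr <- c(paste0("# peak_positions: ", paste(trace$peak_positions, collapse = ",")),
           paste0("# positions: ", paste(trace$positions, collapse = ",")),
           paste0("# peak_width: ", trace$peak_width),
           paste0("# peak_spacing: ", trace$peak_spacing),
           paste0("# grid_step: ", trace$grid_step))
  writeLines(hdr, path)
  readr::write_tsv(trace$channels, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 20)
  grab <- function(key, cast = as.numeric) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    cast(strsplit(sub(paste0("^# ", key, ": "), "", ln[1]), ",")[[1]])
  }
  channels <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  structure(list(channels = channels,
                 peak_positions = grab("peak_positions"),
                 positions = grab("positions", as.integer),
                 peak_width = grab("peak_width"),
                 peak_spacing = grab("peak_spacing"),
                 grid_step = grab("grid_step")),
            class = "trace")
}

#' Read and write peak tables
#'
#' @param table A `peak_table`.
#' @param path File path.
#' @return `read_peak_table()` returns a `peak_table`; the writer returns
#'   `path` invisibly.
#' @export
write_peak_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  out <- as_tibble(d)
  class(out) <- c("peak_table", class(tibble()))
  out
}

#' Write called regions as a 1-based inclusive interval table
#'
#' Not BED: coordinates are 1-based inclusive, and the header says so
#' explicitly. Set `bed = TRUE` for a 0-based half-open BED-style export.
#'
#' @param regions Output of [segment_regions()].
#' @param path File path.
#' @param bed Use BED-style 0-based half-open coordinates instead.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, bed = FALSE) {
  if (bed) {
    out <- dplyr::mutate(regions, start = .data$start - 1L)
    writeLines("# BED-style 0-based half-open coordinates", path)
  } else {
    out <- regions
    writeLines("# coordinates are 1-based inclusive", path)
  }
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write filter-partitioning binding tables
#'
#' CSV with columns `concentration_nM`, `fraction_bound`, and optional
#' `replicate`.
#'
#' @param data A binding dataset tibble.
#' @param path File path.
#' @return `read_binding_table()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_binding_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_binding_table
#' @export
read_binding_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a Hill fit as JSON
#'
#' @param fit A `hill_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hill_fit <- function(fit, path) {
  jsonlite::write_json(
    list(A = unname(fit$coefficients[["A"]]),
         n = unname(fit$coefficients[["n"]]),
         k_half_nM = unname(fit$coefficients[["k_half"]]),
         r_squared = fit$r_squared,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write a difference profile with its calls
#'
#' Tab-delimited `position`, `delta`, `call` (`protection`,
#' `enhancement`, or `.`); masked positions carry the `-999` sentinel.
#'
#' @param diff A `difference_profile`.
#' @param calls A `change_calls` tibble for the same profile.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_difference_profile <- function(diff, calls, path) {
  call_at <- setNames(calls$direction, calls$position)
  out <- tibble(
    position = diff$position,
    delta = ifelse(diff$masked, -999, diff$delta),
    call = dplyr::coalesce(call_at[as.character(diff$position)], "."))
  writeLines("# bound-minus-free differences; 1-based; -999 = no data", path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
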