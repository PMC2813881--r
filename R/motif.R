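#' Find GNRA tetraloops in a structure model
#'
#' Scans the pairing table for hairpin loops of exactly four unpaired
#' nucleotides closed by a base pair whose loop sequence matches
#' G, N, R, A (5' to 3'), where N is any nucleotide and R is a purine.
#'
#' @param model An [rna_structure()] with sequence and pairing.
#' @return A tibble with one row per GNRA tetraloop: `start`, `end`
#'   (loop coordinates, 1-based inclusive), `loop_seq`, `closing_i`,
#'   `closing_j`, and `label` (the annotated loop element containing the
#'   loop, `NA` if unannotated).
#' @export
find_gnra_tetraloops <- function(model) {
  L <- model$length
  partner <- integer(L)
  if (nrow(model$pairs) > 0) {
    partner[model$pairs$i] <- model$pairs$j
    partner[model$pairs$j] <- model$pairs$i
  }
  hits <- list()
  for (i in seq_len(L - 5L)) {
    j <- i + 5L
    # closed hairpin loop of exactly 4 unpaired nucleotides
    if (partner[i] != j) next
    loop <- (i + 1L):(j - 1L)
    if (any(partner[loop] != 0L)) next
    s <- model$sequence[loop]
    if (s[1] == "G" && s[3] %in% c("A", "G") && s[4] == "A") {
      hits[[length(hits) + 1L]] <- tibble(
        start = loop[1], end = loop[4],
        loop_seq = paste(s, collapse = ""),
        closing_i = i, closing_j = j)
    }
  }
  out <- if (length(hits) == 0) {
    tibble(start = integer(), end = integer(), loop_seq = character(),
           closing_i = integer(), closing_j = integer())
  } else {
    dplyr::bind_rows(hits)
  }
  loop_els <- model$elements[model$elements$kind == "loop", , drop = FALSE]
  out$label <- purrr::map_chr(seq_len(nrow(out)), function(k) {
    pos <- out$start[k]:out$end[k]
    hit <- which(purrr::map_lgl(loop_els$positions, ~ all(pos %in% .x)))
    if (length(hit) > 0) loop_els$label[hit[1]] else NA_character_
  })
  out
}

contact_element_positions <- function(model) {
  labels <- unique(c(model$contacts$loop, model$contacts$receptor))
  if (length(labels) == 0) return(integer())
  sort(unique(unlist(purrr::map(labels, ~ element_positions(model, .x)))))
}

#' Assign significant calls to structural elements and motif classes
#'
#' Each call is assigned to the annotated element containing its position
#' and classified relative to the tetraloop-receptor motifs:
#' `within` if the position lies inside an element that participates in a
#' tetraloop-receptor contact (the tetraloop or its receptor helix),
#' `adjacent` if it lies within `adjacency_k` nucleotides (along the
#' sequence) of such an element, and `distal` otherwise.
#'
#' @param calls A `change_calls` tibble from [call_changes()].
#' @param model An [rna_structure()] with elements and contacts annotated.
#' @param adjacency_k Adjacency distance in nucleotides (default 2).
#' @return The calls tibble with `element`, `kind`, and `adjacency`
#'   columns added.
#' @export
assign_calls <- function(calls, model, adjacency_k = 2) {
  if (nrow(calls) > 0 &&
      (any(calls$position < 1) || any(calls$position > model$length))) {
    abort("call position outside the structure model")
  }
  el <- model$elements
  pos2el <- rep(NA_character_, model$length)
  pos2kind <- rep(NA_character_, model$length)
  for (k in seq_len(nrow(el))) {
    pos2el[el$positions[[k]]] <- el$label[k]
    pos2kind[el$positions[[k]]] <- el$kind[k]
  }
  contact_pos <- contact_element_positions(model)
  adjacency <- function(p) {
    if (length(contact_pos) == 0) return("distal")
    d <- min(abs(contact_pos - p))
    if (d == 0) "within" else if (d <= adjacency_k) "adjacent" else "distal"
  }
  out <- dplyr::mutate(calls,
                       element = pos2el[.data$position],
                       kind = pos2kind[.data$position],
                       adjacency = purrr::map_chr(.data$position, adjacency))
  attr(out, "adjacency_k") <- adjacency_k
  out
}

#' Summarize calls per structural element
#'
#' @param assignments Output of [assign_calls()].
#' @param model The [rna_structure()] the calls were assigned against.
#' @return An `element_summary` tibble: one row per annotated element with
#'   `label`, `kind`, `n_positions`, `n_protected`, `n_enhanced`,
#'   `in_tetraloop_receptor`, and the element-level `adjacency` class.
#' @export
summarize_elements <- function(assignments, model) {
  adjacency_k <- attr(assignments, "adjacency_k") %||% 2
  contact_labels <- unique(c(model$contacts$loop, model$contacts$receptor))
  contact_pos <- contact_element_positions(model)
  el <- model$elements
  purrr::map_dfr(seq_len(nrow(el)), function(k) {
    pos <- el$positions[[k]]
    in_el <- assignments$position %in% pos
    d <- if (length(contact_pos) == 0) Inf else {
      min(purrr::map_dbl(pos, ~ min(abs(contact_pos - .x))))
    }
    tibble(
      label = el$label[k], kind = el$kind[k],
      n_positions = length(pos),
      n_protected = sum(in_el & assignments$direction == "protection"),
      n_enhanced = sum(in_el & assignments$direction == "enhancement"),
      in_tetraloop_receptor = el$label[k] %in% contact_labels,
      adjacency = if (el$label[k] %in% contact_labels) "within"
                  else if (d <= adjacency_k) "adjacent" else "distal")
  })
}

#' Fraction of protections at or adjacent to tetraloop-receptor motifs
#'
#' Operationalizes "almost all significant protections occur in or are
#' immediately adjacent to" the motifs as the fraction of protected
#' positions classed `within` or `adjacent`.
#'
#' @param assignments Output of [assign_calls()].
#' @return A single number in `[0, 1]`, or `NA` (with attribute
#'   `undefined = TRUE` and a warning) when there are no protection calls
#'   - an undefined coverage is reported as such, never as 0.
#' @export
motif_coverage <- function(assignments) {
  prot <- assignments[assignments$direction == "protection", , drop = FALSE]
  if (nrow(prot) == 0) {
    warn("no protection calls: motif coverage is undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  mean(prot$adjacency %in% c("within", "adjacent"))
}

#' Check the three-part protection signature at each motif
#'
#' A protein-stabilized tetraloop-receptor interaction protects
#' (i) the tetraloop itself, (ii) the nucleotides in the receptor helix
#' where the tetraloop docks, and (iii) a region of the receptor helix
#' extending toward the exterior of the RNA. For each annotated contact
#' this reports whether a protection call falls in each of the three
#' segments.
#'
#' @param calls A `change_calls` tibble (an [assign_calls()] result also
#'   works).
#' @param model An [rna_structure()] with tetraloop-receptor contacts.
#' @return A tibble with one row per motif: `motif`, `loop`, `receptor`,
#'   `loop_protected`, `receptor_protected`, `extension_protected`,
#'   `complete`.
#' @export
signature_check <- function(calls, model) {
  ct <- model$contacts
  if (nrow(ct) == 0) {
    return(tibble(motif = character(), loop = character(),
                  receptor = character(), loop_protected = logical(),
                  receptor_protected = logical(),
                  extension_protected = logical(), complete = logical()))
  }
  prot_pos <- calls$position[calls$direction == "protection"]
  purrr::map_dfr(seq_len(nrow(ct)), function(k) {
    lp <- any(ct$loop_positions[[k]] %in% prot_pos)
    rp <- any(ct$receptor_positions[[k]] %in% prot_pos)
    ep <- any(ct$extension_positions[[k]] %in% prot_pos)
    tibble(motif = paste0(ct$loop[k], "-", ct$receptor[k]),
           loop = ct$loop[k], receptor = ct$receptor[k],
           loop_protected = lp, receptor_protected = rp,
           extension_protected = ep, complete = lp && rp && ep)
  })
}
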