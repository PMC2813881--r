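#' RNA secondary-structure model with element and tertiary-contact annotation
#'
#' An `rna_structure` bundles everything the footprinting pipeline needs to
#' know about one RNA: its sequence, base pairs, named structural elements
#' (helices `P2`, `P5`, ..., loops `L2`, `L9`, junctions, exons), any
#' annotated GNRA tetraloop-receptor tertiary contacts, and per-nucleotide
#' solvent accessibility for the protein-free and protein-bound states.
#' Coordinates are 1-based throughout, matching the CT-file convention.
#'
#' @param name Character scalar identifying the RNA.
#' @param sequence Character vector of single nucleotides (`A`/`C`/`G`/`U`)
#'   or a single string.
#' @param pairs Tibble or data frame with integer columns `i`, `j`
#'   (`i < j`), each position paired at most once.
#' @param elements Tibble with columns `label`, `kind`
#'   (`helix`/`loop`/`junction`/`exon`) and list-column `positions`.
#' @param contacts Tibble describing tetraloop-receptor contacts, with
#'   columns `loop`, `receptor` (element labels) and list-columns
#'   `loop_positions`, `receptor_positions`, `extension_positions`.
#' @param accessibility_free,accessibility_bound Numeric vectors, one value
#'   per nucleotide in `[0, 1]` (1 = fully solvent exposed); `NA` allowed
#'   when unknown (e.g. structures read from files).
#'
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(name, sequence, pairs = NULL, elements = NULL,
                          contacts = NULL, accessibility_free = NULL,
                          accessibility_bound = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  sequence[sequence == "T"] <- "U"
  L <- length(sequence)
  if (is.null(pairs)) pairs <- tibble(i = integer(), j = integer())
  pairs <- as_tibble(pairs)
  if (is.null(elements)) {
    elements <- tibble(label = character(), kind = character(),
                       positions = list())
  }
  elements <- as_tibble(elements)
  if (is.null(contacts)) {
    contacts <- tibble(loop = character(), receptor = character(),
                       loop_positions = list(), receptor_positions = list(),
                       extension_positions = list())
  }
  contacts <- as_tibble(contacts)
  if (is.null(accessibility_free)) accessibility_free <- rep(NA_real_, L)
  if (is.null(accessibility_bound)) accessibility_bound <- accessibility_free

  model <- structure(
    list(name = name, sequence = sequence, length = L, pairs = pairs,
         elements = elements, contacts = contacts,
         accessibility_free = accessibility_free,
         accessibility_bound = accessibility_bound),
    class = "rna_structure")
  validate_rna_structure(model)
  model
}

validate_rna_structure <- function(model) {
  L <- model$length
  if (!all(model$sequence %in% c("A", "C", "G", "U", "N"))) {
    abort("sequence must contain only A/C/G/U (or N) characters")
  }
  p <- model$pairs
  if (nrow(p) > 0) {
    if (any(p$i >= p$j)) abort("every base pair must have i < j")
    all_pos <- c(p$i, p$j)
    if (any(duplicated(all_pos))) abort("a position is paired more than once")
    if (any(all_pos < 1L | all_pos > L)) abort("pair position outside sequence")
  }
  el <- model$elements
  if (nrow(el) > 0) {
    struct_pos <- unlist(el$positions[el$kind %in% c("helix", "loop")])
    if (any(duplicated(struct_pos))) {
      abort("helix/loop elements must not share positions")
    }
    if (any(unlist(el$positions) < 1L) || any(unlist(el$positions) > L)) {
      abort("element position outside sequence")
    }
  }
  ct <- model$contacts
  if (nrow(ct) > 0) {
    missing <- setdiff(c(ct$loop, ct$receptor), el$label)
    if (length(missing) > 0) {
      abort(paste0("tertiary contact references unknown element(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  for (acc in list(model$accessibility_free, model$accessibility_bound)) {
    if (length(acc) != L) abort("accessibility vector length must equal sequence length")
    ok <- is.na(acc) | (acc >= 0 & acc <= 1)
    if (!all(ok)) abort("accessibility values must lie in [0, 1]")
  }
  invisible(model)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$name, ": ", x$length, " nt, ",
      nrow(x$pairs), " base pairs, ", nrow(x$elements), " elements, ",
      nrow(x$contacts), " tetraloop-receptor contact(s)\n", sep = "")
  invisible(x)
}

#' Positions belonging to a named structural element
#'
#' @param model An [rna_structure()].
#' @param label Element label, e.g. `"P5"`.
#' @return Integer vector of 1-based positions.
#' @export
element_positions <- function(model, label) {
  hit <- which(model$elements$label == label)
  if (length(hit) == 0) abort(paste0("no element labelled '", label, "'"))
  sort(unlist(model$elements$positions[hit]))
}

complement_rna <- function(x) {
  chartr("ACGU", "UGCA", x)
}

random_nt <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

#' Build a toy group-I-intron-like RNA with two tetraloop-receptor motifs
#'
#' Constructs a deterministic (for a fixed seed) model RNA that mimics the
#' architecture relevant to protein footprinting of a group I intron
#' precursor: two helices (`P2`, `P9`) terminated by GAAA tetraloops
#' (`L2`, `L9`), each docked against a distinct receptor helix (`P8`,
#' `P5`), plus two buried "core" helices (`P4`, `P6`), short flanking
#' exons, and connecting junctions. The layout scales with `length`; the
#' two core helices together cover ~20% of the RNA and carry low free-state
#' solvent accessibility, while all elements engaged in tertiary contacts
#' are highly accessible in the free state. In the bound state,
#' accessibility at the tetraloops, the receptor contact face, and the
#' exterior-facing receptor extension is reduced by `footprint_depth`,
#' reproducing the three-part protection signature of a bound
#' tetraloop-receptor motif.
#'
#' @param length Total RNA length in nucleotides; must be at least 80 so
#'   that both motifs fit.
#' @param seed Integer seed; the model is bit-reproducible for a fixed seed.
#' @param footprint_depth Fractional reduction of accessibility at
#'   protein-contact sites in the bound state, in `(0, 1]`.
#' @return An [rna_structure()] with `accessibility_free` and
#'   `accessibility_bound` filled in.
#' @examples
#' m <- build_toy_structure(length = 120, seed = 1)
#' m$contacts$loop
#' @export
build_toy_structure <- function(length = 540, seed = 1, footprint_depth = 0.8) {
  if (length < 80) {
    abort("length must be at least 80 nucleotides to place two tetraloop-receptor motifs")
  }
  if (footprint_depth <= 0 || footprint_depth > 1) {
    abort("footprint_depth must be in (0, 1]")
  }
  withr::with_seed(seed, build_toy_structure_impl(length, footprint_depth))
}

build_toy_structure_impl <- function(L, footprint_depth) {
  core_w <- 2L * max(2L, round(0.05 * L))   # each core helix; two cover ~20%
  widths <- c(E5 = 2L, P2 = 14L, P4 = core_w, P5 = 16L, P6 = core_w,
              P8 = 16L, P9 = 14L, E3 = 2L)
  gap_total <- L - sum(widths)
  stopifnot(gap_total >= 0)
  gaps <- rep(gap_total %/% 7L, 7L)
  extra <- gap_total %% 7L
  if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L

  # sequential layout: E5 J1 P2 J2 P4 J3 P5 J4 P6 J5 P8 J6 P9 J7 E3
  order_blocks <- c("E5", "J1", "P2", "J2", "P4", "J3", "P5", "J4",
                    "P6", "J5", "P8", "J6", "P9", "J7", "E3")
  block_w <- c(widths["E5"], gaps[1], widths["P2"], gaps[2], widths["P4"],
               gaps[3], widths["P5"], gaps[4], widths["P6"], gaps[5],
               widths["P8"], gaps[6], widths["P9"], gaps[7], widths["E3"])
  starts <- cumsum(c(1L, head(block_w, -1)))
  names(starts) <- order_blocks
  span <- function(b) {
    w <- block_w[match(b, order_blocks)]
    if (w == 0) integer() else seq.int(starts[b], length.out = w)
  }

  seqv <- rep(NA_character_, L)
  pairs <- list()
  elements <- list()

  hairpin <- function(label, loop_label, b, stem_bp, loop_seq) {
    w <- 2L * stem_bp + 4L
    pos <- seq.int(b, length.out = w)
    five <- pos[seq_len(stem_bp)]
    three <- rev(pos[(stem_bp + 5L):w])
    loop <- pos[(stem_bp + 1L):(stem_bp + 4L)]
    strand <- random_nt(stem_bp)
    seqv[five] <<- strand
    seqv[three] <<- complement_rna(strand)
    seqv[loop] <<- strsplit(loop_seq, "")[[1]]
    pairs[[length(pairs) + 1L]] <<- tibble(i = five, j = rev(pos[(stem_bp + 5L):w]))
    elements[[length(elements) + 1L]] <<-
      tibble(label = label, kind = "helix", positions = list(sort(c(five, pos[(stem_bp + 5L):w]))))
    elements[[length(elements) + 1L]] <<-
      tibble(label = loop_label, kind = "loop", positions = list(loop))
    list(stem5 = five, stem3 = sort(pos[(stem_bp + 5L):w]), loop = loop, all = pos)
  }

  core_helix <- function(label, b, w) {
    half <- w %/% 2L
    pos <- seq.int(b, length.out = w)
    five <- pos[seq_len(half)]
    three <- pos[(half + 1L):w]
    strand <- random_nt(half)
    seqv[five] <<- strand
    seqv[rev(three)] <<- complement_rna(strand)
    pairs[[length(pairs) + 1L]] <<- tibble(i = five, j = rev(three))
    elements[[length(elements) + 1L]] <<-
      tibble(label = label, kind = "helix", positions = list(pos))
    pos
  }

  p2 <- hairpin("P2", "L2", starts["P2"], 5L, "GAAA")
  p4 <- core_helix("P4", starts["P4"], widths["P4"])
  p5 <- hairpin("P5", "L5", starts["P5"], 6L, "UUCG")
  p6 <- core_helix("P6", starts["P6"], widths["P6"])
  p8 <- hairpin("P8", "L8", starts["P8"], 6L, "UUCG")
  p9 <- hairpin("P9", "L9", starts["P9"], 5L, "GAAA")

  for (b in c("E5", "E3")) {
    pos <- span(b)
    seqv[pos] <- random_nt(length(pos))
    elements[[length(elements) + 1L]] <-
      tibble(label = b, kind = "exon", positions = list(pos))
  }
  for (k in 1:7) {
    b <- paste0("J", k)
    pos <- span(b)
    if (length(pos) == 0) next
    seqv[pos] <- random_nt(length(pos))
    elements[[length(elements) + 1L]] <-
      tibble(label = b, kind = "junction", positions = list(pos))
  }

  # receptor geometry: the loop-proximal stem half is the docking face, the
  # outer half (toward the helix base) is the exterior-facing extension
  receptor_faces <- function(hp, stem_bp) {
    rows <- seq_len(stem_bp)
    contact_rows <- rows[rows > stem_bp / 2]
    outer_rows <- rows[rows <= stem_bp / 2]
    contact <- sort(c(hp$stem5[contact_rows], rev(hp$stem3)[contact_rows]))
    outer <- sort(c(hp$stem5[outer_rows], rev(hp$stem3)[outer_rows]))
    list(contact = contact, extension = outer)
  }
  f8 <- receptor_faces(p8, 6L)
  f5 <- receptor_faces(p5, 6L)

  contacts <- tibble(
    loop = c("L2", "L9"),
    receptor = c("P8", "P5"),
    loop_positions = list(p2$loop, p9$loop),
    receptor_positions = list(f8$contact, f5$contact),
    extension_positions = list(f8$extension, f5$extension))

  low_pos <- c(p4, p6)
  acc_free <- runif(L, 0.75, 1.0)
  acc_free[low_pos] <- runif(length(low_pos), 0.10, 0.20)

  protected <- sort(unique(c(unlist(contacts$loop_positions),
                             unlist(contacts$receptor_positions),
                             unlist(contacts$extension_positions))))
  acc_bound <- acc_free
  acc_bound[protected] <- acc_free[protected] * (1 - footprint_depth)

  rna_structure(
    name = sprintf("toy_bI3_like_%dnt", L),
    sequence = seqv,
    pairs = dplyr::bind_rows(pairs),
    elements = dplyr::bind_rows(elements),
    contacts = contacts,
    accessibility_free = acc_free,
    accessibility_bound = acc_bound)
}
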