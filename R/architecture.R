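# Muscle architecture: per-muscle mass, fibre length, PCSA and maximum force.

#' Jaw muscle part names
#'
#' Canonical identifiers of the muscle parts represented in the model: the
#' superficial masseter (with the anterior deep masseter grouped into it),
#' posterior deep masseter, anterior and posterior zygomaticomandibularis,
#' superficial and deep temporalis, medial and lateral pterygoid (the jaw
#' closers), and the digastric (the jaw opener).
#'
#' @return Character vector of muscle part names.
#' @export
muscle_parts <- function() {
  c(
    "superficial_masseter",
    "posterior_deep_masseter",
    "anterior_zygomaticomandibularis",
    "posterior_zygomaticomandibularis",
    "superficial_temporalis",
    "deep_temporalis",
    "medial_pterygoid",
    "lateral_pterygoid",
    "digastric"
  )
}

jaw_closer_parts <- function() setdiff(muscle_parts(), "digastric")

#' Physiological cross-sectional area of a muscle
#'
#' PCSA = mass * cos(pennation) / (density * fibre_length), the standard
#' fibre-architecture estimate. Pennation defaults to zero (unmeasured for
#' the rabbit jaw closers) and density to 1.05 g cm^-3, the standard muscle
#' tissue density.
#'
#' @param mass Muscle mass in grams.
#' @param fibre_length Fibre length in centimetres (> 0).
#' @param pennation Pennation angle in degrees (default 0).
#' @param density Muscle density in g cm^-3 (default 1.05).
#' @return PCSA in cm^2. Vectorised over its arguments.
#' @examples
#' compute_pcsa(2.0, 0.8) # superficial masseter, ~2.38 cm^2
#' @export
compute_pcsa <- function(mass, fibre_length, pennation = 0, density = 1.05) {
  stopifnot(is.numeric(mass), is.numeric(fibre_length))
  if (any(mass < 0) || any(pennation < 0)) {
    stop("mass and pennation must be non-negative", call. = FALSE)
  }
  if (any(fibre_length <= 0) || any(density <= 0)) {
    stop("fibre_length and density must be positive", call. = FALSE)
  }
  mass * cos(pennation * pi / 180) / (density * fibre_length)
}

#' Maximum isometric muscle force from PCSA
#'
#' Maximum force = PCSA x muscle stress. The default stress of 25 N cm^-2 is
#' an average across mammalian muscle.
#'
#' @param pcsa Physiological cross-sectional area in cm^2 (>= 0).
#' @param muscle_stress Muscle stress in N cm^-2 (> 0, default 25).
#' @return Maximum force in newtons.
#' @examples
#' max_muscle_force(2.436) # 60.9 N
#' @export
max_muscle_force <- function(pcsa, muscle_stress = 25) {
  if (any(pcsa < 0)) stop("pcsa must be non-negative", call. = FALSE)
  if (any(muscle_stress <= 0)) stop("muscle_stress must be positive", call. = FALSE)
  pcsa * muscle_stress
}

#' Rabbit jaw-muscle architecture table
#'
#' The reference architecture of the adult rabbit jaw closers: dissection
#' masses, literature fibre lengths, PCSA and maximum force at a muscle
#' stress of 25 N cm^-2. The printed maximum forces are authoritative for
#' the model; mass, fibre length and PCSA are provenance metadata (the
#' temporalis and pterygoid rows are not exactly reproducible from the
#' mass/length formula and are kept as published).
#'
#' The temporalis is split into its superficial (6.2 N) and deep (30.9 N)
#' parts, which sum to the published whole-muscle 37.1 N. The digastric
#' (jaw opener) has no published maximum force; it defaults to 10 N and is
#' used only for jaw opening.
#'
#' @param muscle_stress Muscle stress in N cm^-2 used to rescale maximum
#'   forces relative to the reference 25 N cm^-2.
#' @param digastric_max_force Maximum force assigned to each digastric, N.
#' @param split_temporalis If `TRUE` (default) report superficial and deep
#'   temporalis as separate rows; otherwise a single temporalis row.
#' @return A tibble with columns `muscle`, `mass`, `fibre_length`, `pcsa`,
#'   `max_force` (one side; both sides are assumed symmetric).
#' @export
rabbit_muscle_architecture <- function(muscle_stress = 25,
                                       digastric_max_force = 10,
                                       split_temporalis = TRUE) {
  base <- tibble::tribble(
    ~muscle,                            ~mass, ~fibre_length, ~pcsa, ~max_force,
    "superficial_masseter",              2.0,   0.8,           2.4,   60.9,
    "posterior_deep_masseter",           0.3,   0.7,           0.4,   10.3,
    "anterior_zygomaticomandibularis",   0.5,   0.8,           0.6,   15.0,
    "posterior_zygomaticomandibularis",  0.3,   0.7,           0.4,   10.5,
    "temporalis",                        1.1,   0.8,           1.5,   37.1,
    "medial_pterygoid",                  1.5,   0.6,           2.5,   62.3,
    "lateral_pterygoid",                 0.3,   0.3,           0.4,   9.8
  )
  if (split_temporalis) {
    ti <- which(base$muscle == "temporalis")
    total <- base$max_force[ti]
    sup <- base[ti, ]
    sup$muscle <- "superficial_temporalis"
    sup$max_force <- 6.2
    sup$mass <- NA_real_
    sup$pcsa <- NA_real_
    deep <- base[ti, ]
    deep$muscle <- "deep_temporalis"
    deep$max_force <- total - 6.2
    deep$mass <- NA_real_
    deep$pcsa <- NA_real_
    base <- dplyr::bind_rows(base[seq_len(ti - 1), ], sup, deep,
                             base[-seq_len(ti), ])
  }
  dig <- tibble::tibble(
    muscle = "digastric", mass = NA_real_, fibre_length = NA_real_,
    pcsa = NA_real_, max_force = digastric_max_force
  )
  out <- dplyr::bind_rows(base, dig)
  out$max_force <- out$max_force * muscle_stress / 25
  out
}

#' Allocate muscle strands per side
#'
#' Distributes a per-side strand budget across muscle parts proportionally
#' to maximum force, with a minimum number of strands per part; any
#' remainder is assigned to (or taken from) the superficial masseter, the
#' strongest and most architecturally heterogeneous muscle. The default
#' budget of 75 strands per side gives 150 in the whole model.
#'
#' @param architecture Architecture tibble as from
#'   [rabbit_muscle_architecture()].
#' @param n_per_side Total strands per side (default 75).
#' @param min_strands Minimum strands per muscle part (default 3).
#' @return Named integer vector of strand counts (one side).
#' @export
allocate_strands <- function(architecture, n_per_side = 75, min_strands = 3) {
  f <- architecture$max_force
  names(f) <- architecture$muscle
  if (n_per_side < min_strands * length(f)) {
    stop("strand budget smaller than the per-muscle minimum", call. = FALSE)
  }
  raw <- f / sum(f) * n_per_side
  n <- pmax(floor(raw), min_strands)
  rem <- n_per_side - sum(n)
  n["superficial_masseter"] <- n["superficial_masseter"] + rem
  if (n["superficial_masseter"] < min_strands) {
    stop("strand allocation failed: superficial masseter below minimum",
         call. = FALSE)
  }
  stats::setNames(as.integer(n), names(f))
}
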