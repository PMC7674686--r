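#' Packaged TNF-superfamily survey of ten vertebrates
#'
#' The package ships, as plain-text fixtures, a survey of tumor necrosis
#' factor superfamily (TNFSF) genes in ten vertebrates: three agnathans
#' (the hagfish *Eptatretus burgeri* and the lampreys *Petromyzon marinus*
#' and *Lethenteron camtschaticum*), two chondrichthyans (*Rhincodon
#' typus*, *Callorhinchus milii*), three actinopterygians (*Danio rerio*,
#' *Takifugu rubripes*, *Lepisosteus oculatus*), the sarcopterygian
#' *Latimeria chalumnae*, and *Homo sapiens*.  Sequences are classified
#' into 24 orthology groups organised in five gene clusters (TNF, EDA,
#' FASL, CD40L and 4-1BBL).
#'
#' `tnfsf_counts()` returns the species-by-group count matrix;
#' `tnfsf_tree()` the rooted species tree with the two ancestral
#' vertebrate WGDs on the vertebrate stem and the teleost-specific WGD on
#' the Danio+Takifugu stem; `tnfsf_constraints()` the origin-constraint
#' table encoding the five-cluster model (three pre-WGD progenitors,
#' thirteen WGD2 ohnologs, and the tandem-duplicate groups).
#'
#' @return A `count_matrix`, `species_tree` or `origin_constraints` object.
#' @name tnfsf_fixture
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "paralogon")
  if (p == "") plg_lookup_error(sprintf("missing packaged fixture '%s'", file))
  p
}

#' @rdname tnfsf_fixture
#' @export
tnfsf_counts <- function() read_count_matrix(fixture_path("tnfsf_counts.tsv"))

#' @rdname tnfsf_fixture
#' @export
tnfsf_tree <- function() {
  read_species_tree(fixture_path("tnfsf_species_tree.nwk"),
                    fixture_path("tnfsf_wgd_events.tsv"))
}

#' @rdname tnfsf_fixture
#' @export
tnfsf_constraints <- function() {
  read_constraints(fixture_path("tnfsf_origin_constraints.tsv"))
}
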