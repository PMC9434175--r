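# Shared fixtures for screen tests; everything is generated in code.

tf_ids <- function(n) sprintf("tf%02d", seq_len(n))

unordered_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# planted effect for each record of an interaction table (0 when none)
planted_effects <- function(records, truth) {
  pe <- truth$pair_effects
  m <- match(unordered_key(records$query_id, records$array_id),
             unordered_key(pe$query_id, pe$array_id))
  ifelse(is.na(m), 0, pe$effect[m])
}

# a uniform single-plate grid at 768 density
uniform_plate <- function(size = 800, plate_id = "p1") {
  cells <- expand.grid(col = 1:32, row = 1:24)
  tibble::tibble(
    plate_id = plate_id, screen_id = "s1", condition = "selection",
    replicate = 1L, row = as.integer(cells$row), col = as.integer(cells$col),
    size = size
  )
}

full_layout_768 <- function(n_strains = 91) {
  build_sl_layout(tf_ids(n_strains), replicates = 6, density = 768)
}
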