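# Shared fixtures.  Phantom pairs are built once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

# conformed/normalized phantom with tight box and true-center fixed crop
make_fixture_pair <- function(i, geometry, seed = 100) {
  ph <- generate_phantom(phantom_spec(shape = geometry$input_shape,
                                      seed = derive_seed(seed, "fix", i)))
  vol <- normalize_intensity(ph$volume)
  box <- bbox_target(ph$mask)
  fixed <- finalize_bbox(c(box$start, box$lengths) * geometry$downsample,
                         geometry, vol_shape = dim(vol$data))
  list(volume = vol, mask = ph$mask, box = box, fixed = fixed,
       cropped = list(volume = crop(vol, fixed), mask = crop(ph$mask, fixed)))
}

desk_fixture_pairs <- function(n, seed = 100) {
  key <- paste0("pairs_", n, "_", seed)
  got <- get0(key, envir = .fixture_env)
  if (!is.null(got)) return(got)
  geo <- desk_geometry()
  out <- lapply(seq_len(n), make_fixture_pair, geometry = geo, seed = seed)
  assign(key, out, envir = .fixture_env)
  out
}

# tiny geometry for fast network unit tests
tiny_geometry <- function() {
  pipeline_geometry(input_shape = c(32, 32, 32), crop_lengths = c(16, 16, 16))
}

mean_foreground_dice <- function(pred_labels, truth_labels, unknown = 0L) {
  ids <- setdiff(sort(unique(as.vector(truth_labels))), unknown)
  mean(vapply(ids, function(id)
    dsc(pred_labels == id, truth_labels == id), numeric(1)))
}
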