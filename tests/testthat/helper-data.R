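# Shared small fixtures, built once per test run.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .test_cache)) assign(key, force(expr), .test_cache)
  get(key, .test_cache)
}

# A small rendered scene reused across tests.
tiny_scene <- function(seed = 5) {
  cached(paste0("scene", seed), {
    pose <- generate_subject_pose(seed, "supine", height = 64, width = 48)
    list(pose = pose,
         frame = render_frame(pose, seed = seed, height = 64, width = 48))
  })
}

# A small on-disk manifest reused by manifest-facing tests.
tiny_manifest <- function() {
  cached("tiny_manifest", {
    d <- file.path(tempdir(), "irbedpose-tiny-manifest")
    build_manifest(6, 4, 4, 2, 2, seed = 31, out_dir = d,
                   height = 64, width = 48)
  })
}

random_pose <- function(seed, height = 64, width = 48) {
  generate_subject_pose(seed, "supine", height = height, width = width)
}
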