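Place the archived field survey tables here to let the pipeline (and the
optional reproduction test) recompute the published results:

  shoals.csv    - shoal table: shoal_id, location_id, observer_id, plus one
                  integer count column per species (catalog labels)
  foraging.csv  - foraging table: individual_id, species, length_cm,
                  shoal_size, shoal_type, location_id, observer_id,
                  duration_s, n_bites, n_bouts

These files are not redistributed with the package.
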