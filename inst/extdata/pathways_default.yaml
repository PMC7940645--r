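# Default neurotransmitter pathway definitions: two dopaminergic and five
# cholinergic projection systems, bilateral region names (one left + one
# right column per region; brainstem structures are midline).
#
# The underlying anatomical parcellation is deliberately coarse and
# editable: the mapping of projection systems onto named parcels (in
# particular which parcels make up the "remaining" association cortices of
# the Ch4 lateral capsular division) is a granularity choice, not an
# anatomical ground truth. Supply your own file with the same schema to
# override it.
pathways:
  - name: striatocortical
    rois:
      - {name: dorsal_caudate_L, laterality: left}
      - {name: dorsal_caudate_R, laterality: right}
      - {name: dorsal_putamen_L, laterality: left}
      - {name: dorsal_putamen_R, laterality: right}
      - {name: premotor_frontal_L, laterality: left}
      - {name: premotor_frontal_R, laterality: right}
      - {name: motor_cortex_L, laterality: left}
      - {name: motor_cortex_R, laterality: right}
      - {name: dorsolateral_prefrontal_L, laterality: left}
      - {name: dorsolateral_prefrontal_R, laterality: right}
      - {name: somatosensory_L, laterality: left}
      - {name: somatosensory_R, laterality: right}
  - name: mesolimbic
    rois:
      - {name: ventral_striatum_L, laterality: left}
      - {name: ventral_striatum_R, laterality: right}
      - {name: ventral_frontal_L, laterality: left}
      - {name: ventral_frontal_R, laterality: right}
      - {name: medial_frontal_L, laterality: left}
      - {name: medial_frontal_R, laterality: right}
      - {name: anterior_cingulate_L, laterality: left}
      - {name: anterior_cingulate_R, laterality: right}
      - {name: middle_cingulate_L, laterality: left}
      - {name: middle_cingulate_R, laterality: right}
      - {name: amygdala_L, laterality: left}
      - {name: amygdala_R, laterality: right}
      - {name: parahippocampal_L, laterality: left}
      - {name: parahippocampal_R, laterality: right}
  - name: ch1_3
    rois:
      - {name: hippocampus_L, laterality: left}
      - {name: hippocampus_R, laterality: right}
      - {name: hypothalamus_L, laterality: left}
      - {name: hypothalamus_R, laterality: right}
      - {name: olfactory_cortex_L, laterality: left}
      - {name: olfactory_cortex_R, laterality: right}
      - {name: parahippocampal_L, laterality: left}
      - {name: parahippocampal_R, laterality: right}
  - name: ch4_medial
    rois:
      - {name: anterior_cingulate_L, laterality: left}
      - {name: anterior_cingulate_R, laterality: right}
      - {name: posterior_cingulate_L, laterality: left}
      - {name: posterior_cingulate_R, laterality: right}
      - {name: retrosplenial_L, laterality: left}
      - {name: retrosplenial_R, laterality: right}
      - {name: orbitofrontal_L, laterality: left}
      - {name: orbitofrontal_R, laterality: right}
  - name: ch4_lateral_perisylvian
    rois:
      - {name: olfactory_cortex_L, laterality: left}
      - {name: olfactory_cortex_R, laterality: right}
      - {name: superior_temporal_L, laterality: left}
      - {name: superior_temporal_R, laterality: right}
      - {name: insula_L, laterality: left}
      - {name: insula_R, laterality: right}
      - {name: frontoparietal_operculum_L, laterality: left}
      - {name: frontoparietal_operculum_R, laterality: right}
  - name: ch4_lateral_capsular
    rois:
      - {name: superior_frontal_L, laterality: left}
      - {name: superior_frontal_R, laterality: right}
      - {name: middle_frontal_L, laterality: left}
      - {name: middle_frontal_R, laterality: right}
      - {name: inferior_frontal_L, laterality: left}
      - {name: inferior_frontal_R, laterality: right}
      - {name: superior_parietal_L, laterality: left}
      - {name: superior_parietal_R, laterality: right}
      - {name: inferior_parietal_L, laterality: left}
      - {name: inferior_parietal_R, laterality: right}
      - {name: precuneus_L, laterality: left}
      - {name: precuneus_R, laterality: right}
      - {name: middle_temporal_L, laterality: left}
      - {name: middle_temporal_R, laterality: right}
      - {name: inferior_temporal_L, laterality: left}
      - {name: inferior_temporal_R, laterality: right}
      - {name: occipital_L, laterality: left}
      - {name: occipital_R, laterality: right}
      - {name: amygdala_L, laterality: left}
      - {name: amygdala_R, laterality: right}
  - name: ch5_6
    rois:
      - {name: thalamus_L, laterality: left}
      - {name: thalamus_R, laterality: right}
      - {name: ventral_striatum_L, laterality: left}
      - {name: ventral_striatum_R, laterality: right}
      - {name: dorsal_caudate_L, laterality: left}
      - {name: dorsal_caudate_R, laterality: right}
      - {name: dorsal_putamen_L, laterality: left}
      - {name: dorsal_putamen_R, laterality: right}
      - {name: globus_pallidus_L, laterality: left}
      - {name: globus_pallidus_R, laterality: right}
      - {name: pons, laterality: midline}
      - {name: midbrain, laterality: midline}
      - {name: medulla, laterality: midline}
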