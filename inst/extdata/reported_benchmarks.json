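{
  "comment": "Published Top-k accuracies (percent) of the Danish fungi recognition systems, used only for arithmetic-consistency checks of headline error-reduction figures.",
  "danish_fungi_2021_top1": {
    "deployed_cnn_2018": 69.28,
    "vit_large_df20_metadata": 83.64
  },
  "df20_384_top1": {
    "best_model": 80.45,
    "metadata_gain_all_three": 2.95
  },
  "fungi18_validation_top1": {
    "single_cnn_single_crop": 48.8,
    "single_cnn_single_crop_uniform_prior": 52.6
  },
  "fungi18_test_private_top3": {
    "cnn_2018": 70.69,
    "vit_df20": 77.28
  }
}
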