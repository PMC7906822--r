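"""Convert a BCI Competition IV 2a GDF session to Feather/CSV/JSON.

Usage: python gdf_convert.py session.gdf out_prefix

Writes out_prefix + {_signals.feather, _events.csv, _meta.json}. Signals are
the 22 EEG channels (EOG dropped) as one row per channel; events hold the
0-based trial-onset sample and class 1-4 mapped from the cue annotations
769-772 (left hand, right hand, foot, tongue). Trial onsets are placed 2 s
before the cue so that downstream windowing can use times relative to trial
start, matching the paradigm timing.
"""
import json
import sys

import mne
import numpy as np
import pandas as pd

CUE_TO_CLASS = {"769": 1, "770": 2, "771": 3, "772": 4}
EOG = ("EOG-left", "EOG-central", "EOG-right")
CUE_ONSET_S = 2.0
TRIAL_LENGTH_S = 7.5


def main(path, out):
    raw = mne.io.read_raw_gdf(path, preload=True, verbose="error")
    raw.drop_channels([ch for ch in raw.ch_names if ch in EOG or "EOG" in ch])
    fs = float(raw.info["sfreq"])
    sig = raw.get_data() * 1e6  # volts -> microvolts
    onsets, classes = [], []
    for onset, desc in zip(raw.annotations.onset, raw.annotations.description):
        if desc in CUE_TO_CLASS:
            onsets.append(int(round((onset - CUE_ONSET_S) * fs)))
            classes.append(CUE_TO_CLASS[desc])
    pd.DataFrame(sig.T).to_feather(out + "_signals.feather")
    # feather stores column-major frames; R re-transposes to channel x sample
    pd.DataFrame({"onset_sample": onsets, "class": classes}).to_csv(
        out + "_events.csv", index=False)
    meta = {"subject_id": path.split("/")[-1].split(".")[0],
            "sampling_rate": fs, "trial_length_s": TRIAL_LENGTH_S}
    with open(out + "_meta.json", "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
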