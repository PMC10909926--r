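# Recording JSON schema (schema_version 1)

Units are fixed at this boundary: metres, seconds, newtons, Hz.
Coordinates are a right-handed camera frame; after load-time
canonicalisation x is anterior, y is up, z points to the subject's right.

```json
{
  "schema_version": 1,
  "subject_id": "S1",
  "affected_side": "left | right",
  "clips": [
    {
      "motion_id": "M1",            // one of M1..M21
      "side": "affected | healthy",
      "fs": 30,                     // Hz, must exceed 24
      "body": {
        "t": [0, 0.033, ...],       // strictly increasing seconds
        "joints": {                 // joint name -> n x 3 positions (m)
          "PELVIS": [[x, y, z], ...],
          "SPINE_CHEST": [...], "NECK": [...], "NOSE": [...],
          "SHOULDER_L": [...], "SHOULDER_R": [...],
          "ELBOW_L": [...], "ELBOW_R": [...],
          "WRIST_L": [...], "WRIST_R": [...],
          "HANDTIP_L": [...], "HANDTIP_R": [...],
          "HIP_L": [...], "HIP_R": [...]
        }
      },
      "hand": {                     // optional 21-point hand landmarks
        "t": [...],
        "landmarks": [ [[x,y,z] x21], ... ]   // index 0 = wrist origin
      }
    }
  ],
  "force_frames": [
    {
      "motion_id": "M16",           // grasp motions M16..M20 only
      "side": "affected",
      "t": 0.1,
      "grid": [256 numbers]         // row-major 16x16, newtons, >= 0
    }
  ]
}
```

Force frames may alternatively be supplied as CSV with header
`motion_id,side,t,c1..c256` (row-major cells).

Validation rules: every motion present on one side must be present on the
other ("unpaired side" otherwise); NaN/infinite coordinates or forces are
rejected at parse time; grids must have exactly 256 non-negative cells.
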