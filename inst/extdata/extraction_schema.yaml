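# Default pattern schema for note extraction.
#
# One entry per extractable variable. Each entry lists ordered patterns
# (matched case-insensitively; first match wins) and a converter that recodes
# the captured text. Entries may be plain pattern strings with one capture
# group, or pattern/value pairs that assign a fixed code when the pattern
# matches (used for yes/no variables where the phrasing itself carries the
# value). This default set covers the package's shipped template bank; adapt
# it to local note styles by editing a copy and passing its path to
# load_extraction_schema().
variables:
  chart_number:
    converter: integer
    patterns:
      - 'chart[^0-9]{0,12}(\d+)'
  date:
    converter: date
    patterns:
      - '(\d{4}-\d{2}-\d{2})'
  stage:
    converter: stage_roman
    patterns:
      - 'stage\s*:?\s*(iv|iii|ii|i)\b'
  grade:
    converter: grade_letter
    patterns:
      - 'grade\s*:?\s*([abc])\b'
  systolic_bp:
    converter: integer
    patterns:
      - '(?:bp|blood pressure)(?:\s+was)?\s*:?\s*(\d{2,3})\s*(?:/|over)'
  diastolic_bp:
    converter: integer
    patterns:
      - '(?:bp|blood pressure)[^.]{0,14}(?:/|over)\s*(\d{2,3})'
  heart_rate:
    converter: integer
    patterns:
      - '(?:\bhr\b|heart rate(?: of)?|pulse)\s*:?\s*(\d{2,3})'
  stain:
    converter: ordinal
    patterns:
      - '(no|light|medium|heavy)\s+stain'
      - 'tooth stain\s*:\s*(no|light|medium|heavy)'
  smoking:
    converter: flag
    patterns:
      - pattern: 'no smoking history|non-?smoker|denies smoking'
        value: 0
      - pattern: 'smoker|smoking history|smokes'
        value: 1
  plaque:
    converter: ordinal
    patterns:
      - '(no|light|medium|heavy)\s+plaque'
      - 'plaque\s*:\s*(no|light|medium|heavy)'
  calculus:
    converter: ordinal
    patterns:
      - '(no|light|medium|heavy)\s+calculus'
      - 'calculus\s*:\s*(no|light|medium|heavy)'
  bone_loss:
    converter: flag
    patterns:
      - pattern: 'no (?:radiographic )?bone loss'
        value: 0
      - pattern: 'bone loss (?:evident|present)|generalized bone loss|radiographic bone loss'
        value: 1
  tooth_mobility:
    converter: flag
    patterns:
      - pattern: 'no tooth mobility|no mobile teeth'
        value: 0
      - pattern: 'tooth mobility|mobile teeth|mobility detected'
        value: 1
  allergies:
    converter: flag
    patterns:
      - pattern: 'no known allergies|nkda|denies allergies'
        value: 0
      - pattern: 'allergies\s*:\s*yes|drug allergies|reports allergies'
        value: 1
  prior_surgery:
    converter: flag
    patterns:
      - pattern: 'no history of periodontal surgery|no previous fgg'
        value: 0
      - pattern: '\bfgg\b|\bgtr\b|\bgbr\b|periodontal surgery'
        value: 1
  diabetes:
    converter: flag
    patterns:
      - pattern: 'non-?diabetic|no diabetes|denies diabetes'
        value: 0
      - pattern: 'diabet'
        value: 1
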