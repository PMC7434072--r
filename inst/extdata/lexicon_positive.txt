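# Bundled general-purpose positive sentiment lexicon (one token per line).
# Written for this package; deliberately disjoint from the negative list.
admirable
amazing
awesome
beautiful
benefit
best
blessed
brave
bright
brilliant
calm
celebrate
cheerful
cherish
comfort
commend
confident
congratulations
courage
delight
delighted
determined
devoted
earnest
easier
elated
encourage
encouraging
energized
enjoy
enthusiastic
excellent
excited
fabulous
fantastic
favorite
fortunate
friendly
fulfilled
fun
generous
gentle
glad
glorious
good
graceful
grateful
great
happy
healthy
helpful
honored
hope
hopeful
hug
hugs
impressive
inspire
inspiring
joy
joyful
kind
laugh
love
lovely
loyal
lucky
marvelous
motivated
nice
optimistic
outstanding
peaceful
perfect
pleasant
pleased
positive
proud
refreshed
relieved
remarkable
resilient
respect
reward
rewarding
safe
satisfied
smile
splendid
strength
strong
succeed
success
successful
superb
support
supportive
terrific
thankful
thrilled
triumph
trust
uplifting
victory
warm
welcome
win
wonderful
worthy
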